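# Connectome of the four-section spinal locomotor network.
#
# The cord is modeled as four sections (girdle {fore, hind} x side
# {left, right}). Each section holds a rhythm generator (flexor center RG-F
# and extensor center RG-E, both carrying INaP), local inhibitory
# interneurons, commissural interneurons (CINs: V0D, V0V with its V2a relay
# and IniV0V inhibitory relay, V3, CINi) and long propriospinal neurons
# (LPNs: homolateral Sh2-Hom/Ini-Hom, diagonal V0V-diag/V0D-diag).
# Inhibitory LPNs (Ini-Hom, V0D-diag) exist only in the fore (cervical)
# sections: descending-only pathways.

POP_NAMES_FORE <- c("RG-F", "RG-E", "Ini-F", "Ini-E", "V0D", "V2a", "V0V",
                    "IniV0V", "V3", "CINi", "V2a-diag", "V0V-diag",
                    "Sh2-Hom", "Ini-Hom", "V0D-diag")
POP_NAMES_HIND <- POP_NAMES_FORE[1:13]

# source population name -> output sign (+1 excitatory, -1 inhibitory)
POP_SIGN <- c("RG-F" = 1, "RG-E" = 1, "Ini-F" = -1, "Ini-E" = -1,
              "V0D" = -1, "V2a" = 1, "V0V" = 1, "IniV0V" = -1, "V3" = 1,
              "CINi" = -1, "V2a-diag" = 1, "V0V-diag" = 1, "Sh2-Hom" = 1,
              "Ini-Hom" = -1, "V0D-diag" = -1)

# Connection table: one row per pathway, expanded over sections.
# scope: ipsi (same section), contra (same girdle, other side),
#        homo (other girdle, same side), diag (other girdle, other side).
# girdle: source-girdle restriction ("both", "fore", "hind").
CONNECTION_RULES <- data.frame(
  src = c("RG-F", "RG-F", "RG-F", "RG-F", "RG-F",
          "RG-F", "RG-F",
          "RG-E", "RG-E", "RG-E",
          "Ini-F", "Ini-E", "V2a", "V2a-diag", "IniV0V",
          "V0D", "V0V", "V3", "CINi",
          "Ini-Hom", "Sh2-Hom", "Sh2-Hom",
          "V0D-diag", "V0V-diag", "V0V-diag"),
  dst = c("Ini-F", "V0D", "V2a", "V3", "V2a-diag",
          "Ini-Hom", "V0D-diag",
          "Ini-E", "CINi", "Sh2-Hom",
          "RG-E", "RG-F", "V0V", "V0V-diag", "RG-F",
          "RG-F", "IniV0V", "RG-F", "RG-F",
          "RG-F", "RG-F", "RG-F",
          "RG-F", "RG-F", "RG-F"),
  weight = c(0.40, 0.70, 1.00, 0.35, 0.50,
             0.70, 0.50,
             0.40, 0.40, 0.50,
             -1.00, -0.08, 1.00, 0.90, -0.07,
             -0.07, 0.60, 0.03, -0.03,
             -0.01, 0.01, 0.125,
             -0.075, 0.02, 0.065),
  scope = c(rep("ipsi", 15), rep("contra", 4), "homo", "homo", "homo",
            "diag", "diag", "diag"),
  girdle = c(rep("both", 5), "fore", "fore", rep("both", 8),
             rep("both", 4), "fore", "fore", "hind", "fore", "fore", "hind"),
  stringsAsFactors = FALSE
)

pop_id <- function(girdle, side, name) paste(girdle, side, name, sep = "_")

#' Build the intact four-limb locomotor network
#'
#' Constructs the canonical connectome: 56 populations (15 per fore section,
#' 13 per hind section; inhibitory long propriospinal neurons are
#' descending-only and exist in fore sections alone) and 84 directed weighted
#' connections, expanded over the four sections from the pathway table.
#'
#' Brainstem drive coefficients (slope `m`, intercept `b` of the linear drive
#' `m * alpha + b`): extensor centers receive constant excitatory drive
#' (`mE = 0, bE = 0.1`); flexor centers receive drive proportional to alpha
#' (`mE = 0.1, bE = 0`); the inhibitory drive grows with alpha for all V0D
#' populations, local CINs and descending diagonal LPNs alike
#' (`mI = 0.75, bI = 0`), and for the local homologous V0V CINs
#' (`mI = 0.15, bI = 0`). All other populations receive no drive.
#'
#' @return An object of class `cpg_network`: a list with data frames
#'   `populations` (id, name, girdle, side, rhythmogenic, deleted, and the
#'   per-population parameters `C` pF, `gL` nS, `EL` mV, `mE`, `bE`, `mI`,
#'   `bI`) and `connections` (src, dst, weight).
#' @export
#' @examples
#' net <- build_intact_network()
#' nrow(net$populations)  # 56
#' nrow(net$connections)  # 84
build_intact_network <- function() {
  sections <- expand.grid(side = c("left", "right"),
                          girdle = c("fore", "hind"),
                          stringsAsFactors = FALSE)[, c("girdle", "side")]
  pops <- do.call(rbind, lapply(seq_len(nrow(sections)), function(k) {
    g <- sections$girdle[k]; s <- sections$side[k]
    nm <- if (g == "fore") POP_NAMES_FORE else POP_NAMES_HIND
    data.frame(id = pop_id(g, s, nm), name = nm, girdle = g, side = s,
               stringsAsFactors = FALSE)
  }))
  pops$rhythmogenic <- pops$name %in% c("RG-F", "RG-E")
  pops$deleted <- FALSE
  pops$C <- 10
  pops$gL <- ifelse(pops$rhythmogenic, 4.5, 2.8)
  pops$EL <- ifelse(pops$rhythmogenic, -62.5, -60)
  pops$mE <- ifelse(pops$name == "RG-F", 0.1, 0)
  pops$bE <- ifelse(pops$name == "RG-E", 0.1, 0)
  pops$mI <- ifelse(pops$name %in% c("V0D", "V0D-diag"), 0.75,
                    ifelse(pops$name == "V0V", 0.15, 0))
  pops$bI <- 0

  other_side <- c(left = "right", right = "left")
  other_girdle <- c(fore = "hind", hind = "fore")
  conns <- do.call(rbind, lapply(seq_len(nrow(CONNECTION_RULES)), function(r) {
    rule <- CONNECTION_RULES[r, ]
    out <- lapply(seq_len(nrow(sections)), function(k) {
      g <- sections$girdle[k]; s <- sections$side[k]
      if (rule$girdle != "both" && rule$girdle != g) return(NULL)
      dg <- switch(rule$scope, ipsi = g, contra = g,
                   homo = other_girdle[[g]], diag = other_girdle[[g]])
      ds <- switch(rule$scope, ipsi = s, homo = s,
                   contra = other_side[[s]], diag = other_side[[s]])
      src <- pop_id(g, s, rule$src)
      dst <- pop_id(dg, ds, rule$dst)
      data.frame(src = src, dst = dst, weight = rule$weight,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  }))
  rownames(pops) <- rownames(conns) <- NULL
  net <- structure(list(populations = pops, connections = conns),
                   class = "cpg_network")
  validate_network(net)
  net
}

#' Validate a locomotor network object
#'
#' Checks structural invariants: population ids are unique; every connection
#' endpoint exists; each source population has a fixed output sign and all of
#' its outgoing weights carry that sign; rhythmogenic flags, leak parameters
#' and the fore-only placement of inhibitory LPNs are consistent.
#'
#' @param net a `cpg_network`.
#' @return `net`, invisibly; stops on violation.
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "cpg_network"))
  p <- net$populations; cn <- net$connections
  if (anyDuplicated(p$id)) stop("duplicate population ids")
  missing <- setdiff(unique(c(cn$src, cn$dst)), p$id)
  if (length(missing))
    stop("connections reference unknown populations: ",
         paste(missing, collapse = ", "))
  if (!identical(p$rhythmogenic, p$name %in% c("RG-F", "RG-E")))
    stop("rhythmogenic flag must mark exactly the RG-F and RG-E centers")
  if (any(p$gL != ifelse(p$rhythmogenic, 4.5, 2.8)) ||
      any(p$EL != ifelse(p$rhythmogenic, -62.5, -60)))
    stop("leak parameters inconsistent with rhythmogenic flag")
  if (any(p$girdle == "hind" & p$name %in% c("Ini-Hom", "V0D-diag")))
    stop("inhibitory LPNs (Ini-Hom, V0D-diag) are descending-only (fore)")
  src_name <- p$name[match(cn$src, p$id)]
  sgn <- POP_SIGN[src_name]
  if (any(sign(cn$weight) != sgn))
    stop("connection weight sign inconsistent with source population class")
  invisible(net)
}

#' Resolve a population selector to ids
#'
#' Selector tokens (combined with `,`, `;` or `and`, case-insensitive):
#' \itemize{
#'   \item a full id, e.g. `"fore_left_V0V"`;
#'   \item a bare population name, e.g. `"V0V-diag"` (all sections where it
#'     exists), optionally girdle-qualified: `"fore V0V-diag"`
#'     (`cervical`/`lumbar` are accepted for `fore`/`hind`);
#'   \item a class: `"all V0V"` (V0V CINs + V0V-diag LPNs), `"all V0D"`
#'     (V0D CINs + V0D-diag LPNs), `"all V2a"` (V2a + V2a-diag);
#'   \item `"descending LPNs"` (synonym `"cervical-to-lumbar LPNs"`): the
#'     fore-section Ini-Hom, Sh2-Hom, V0D-diag and V0V-diag populations;
#'     `"ascending LPNs"` (`"lumbar-to-cervical LPNs"`): hind-section
#'     Sh2-Hom and V0V-diag.
#' }
#'
#' @param net a `cpg_network`.
#' @param select character vector of selector tokens.
#' @return character vector of population ids (unique, in network order).
#' @export
#' @examples
#' net <- build_intact_network()
#' resolve_selector(net, "all V0V and V0D")
resolve_selector <- function(net, select) {
  p <- net$populations
  if (length(select) == 0) return(character(0))
  tokens <- unlist(strsplit(select, "\\s*(,|;|\\band\\b)\\s*"))
  tokens <- trimws(tokens)
  tokens <- tokens[nzchar(tokens)]
  class_sets <- list(
    "v0v" = c("V0V", "V0V-diag"),
    "v0d" = c("V0D", "V0D-diag"),
    "v2a" = c("V2a", "V2a-diag")
  )
  girdle_words <- c(fore = "fore", cervical = "fore", hind = "hind",
                    lumbar = "hind")
  ids <- character(0)
  lpn_names_desc <- c("Ini-Hom", "Sh2-Hom", "V0D-diag", "V0V-diag")
  lpn_names_asc <- c("Sh2-Hom", "V0V-diag")
  all_ctx <- FALSE   # "all V0V and V0D" distributes "all" over the conjuncts
  for (tok in tokens) {
    lt <- tolower(tok)
    lt <- sub("\\s+neurons?$", "", lt)
    if (grepl("^all\\s+", lt)) {
      all_ctx <- TRUE
      lt <- sub("^all\\s+", "", lt)
    }
    hit <- NULL
    if (lt %in% c("descending lpns", "descending lpn",
                  "cervical-to-lumbar lpns", "cervical-to-lumbar lpn")) {
      hit <- p$id[p$girdle == "fore" & p$name %in% lpn_names_desc]
    } else if (lt %in% c("ascending lpns", "ascending lpn",
                         "lumbar-to-cervical lpns", "lumbar-to-cervical lpn")) {
      hit <- p$id[p$girdle == "hind" & p$name %in% lpn_names_asc]
    } else if (all_ctx && lt %in% names(class_sets)) {
      hit <- p$id[p$name %in% class_sets[[lt]]]
    } else if (lt %in% tolower(p$id)) {
      hit <- p$id[tolower(p$id) == lt]
    } else {
      parts <- strsplit(lt, "\\s+")[[1]]
      if (length(parts) == 2 && parts[1] %in% names(girdle_words)) {
        g <- girdle_words[[parts[1]]]
        hit <- p$id[p$girdle == g & tolower(p$name) == parts[2]]
      } else if (length(parts) == 1 && lt %in% tolower(p$name)) {
        hit <- p$id[tolower(p$name) == lt]
      }
    }
    if (is.null(hit) || length(hit) == 0)
      stop("selector does not resolve to any population: '", tok, "'")
    ids <- c(ids, hit)
  }
  p$id[p$id %in% ids]
}

#' Delete (silence) populations
#'
#' Flags the selected populations as deleted. Deleted populations remain in
#' the state vector and their dynamics are still integrated, but their output
#' is clamped to zero in all downstream synaptic sums (output clamp, not
#' state removal).
#'
#' @param net a `cpg_network`.
#' @param select selector (see [resolve_selector()]); an empty selection is
#'   the identity.
#' @return the network with the selection flagged deleted.
#' @export
#' @examples
#' net <- delete_populations(build_intact_network(), "all V0V")
#' sum(net$populations$deleted)
delete_populations <- function(net, select) {
  ids <- resolve_selector(net, select)
  net$populations$deleted[net$populations$id %in% ids] <- TRUE
  net
}

#' Randomly perturb all connection weights
#'
#' Multiplies every connection weight by an independent normal draw with mean
#' 1 and standard deviation `sigma_p` (untruncated; at the standard deviations
#' used for robustness screening a sign flip is practically impossible).
#'
#' @param net a `cpg_network`.
#' @param sigma_p standard deviation of the multiplicative perturbation
#'   (>= 0).
#' @param seed optional integer seed for reproducibility.
#' @return the perturbed network.
#' @export
perturb_weights <- function(net, sigma_p, seed = NULL) {
  if (sigma_p < 0) stop("sigma_p must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  mult <- stats::rnorm(nrow(net$connections), mean = 1, sd = sigma_p)
  net$connections$weight <- net$connections$weight * mult
  net
}

#' @export
print.cpg_network <- function(x, ...) {
  p <- x$populations
  cat("<cpg_network> ", nrow(p), " populations, ",
      nrow(x$connections), " connections\n", sep = "")
  if (any(p$deleted))
    cat("  deleted:", paste(p$id[p$deleted], collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a network to JSON
#'
#' Writes the populations and connections (including deletion flags and any
#' perturbed weights) as a flat JSON document that [read_network()] restores
#' exactly.
#'
#' @param net a `cpg_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  jsonlite::write_json(list(populations = net$populations,
                            connections = net$connections),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a network from JSON
#'
#' @param path file written by [write_network()].
#' @return a validated `cpg_network`.
#' @export
read_network <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  net <- structure(list(populations = as.data.frame(doc$populations),
                        connections = as.data.frame(doc$connections)),
                   class = "cpg_network")
  validate_network(net)
  net
}
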