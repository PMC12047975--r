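#' Marker map for a two-founder recombinant inbred panel
#'
#' A founder map records the markers available for simulation and scanning:
#' one row per marker with chromosome, genetic position (cM) and physical
#' position (Mb). Positions must be strictly increasing within a chromosome.
#'
#' @param marker character vector of marker names (unique).
#' @param chr chromosome label per marker.
#' @param cM genetic position per marker, centimorgans.
#' @param Mb physical position per marker, megabases.
#' @return A `data.frame` of class `founder_map` with columns
#'   `marker`, `chr`, `cM`, `Mb`.
#' @examples
#' fm <- founder_map(c("m1", "m2"), chr = c("1", "1"), cM = c(0, 10), Mb = c(3, 8))
#' @export
founder_map <- function(marker, chr, cM, Mb) {
  if (length(marker) == 0L) stop("founder map must contain at least one marker")
  n <- length(marker)
  if (length(chr) != n || length(cM) != n || length(Mb) != n)
    stop("marker, chr, cM and Mb must have equal length")
  if (anyDuplicated(marker)) stop("marker names must be unique")
  if (any(!is.finite(cM)) || any(!is.finite(Mb)))
    stop("positions must be finite")
  map <- data.frame(marker = as.character(marker), chr = as.character(chr),
                    cM = as.numeric(cM), Mb = as.numeric(Mb),
                    stringsAsFactors = FALSE)
  for (cc in unique(map$chr)) {
    sub <- map[map$chr == cc, ]
    if (any(diff(sub$cM) <= 0) || any(diff(sub$Mb) <= 0))
      stop("positions must be strictly increasing within chromosome ", cc)
  }
  class(map) <- c("founder_map", "data.frame")
  map
}

#' Default marker map for simulations
#'
#' Evenly spaced markers on a configurable number of autosomes. Defaults give
#' a mouse-like density: 5 chromosomes of 100 cM with a marker every 5 cM and
#' roughly 2 Mb per cM, a coarse stand-in for a genotyped RI panel.
#'
#' @param n_chr number of chromosomes.
#' @param markers_per_chr markers per chromosome.
#' @param spacing_cM inter-marker distance in cM.
#' @param mb_per_cM physical-to-genetic scale (Mb per cM).
#' @return A [founder_map()].
#' @export
default_founder_map <- function(n_chr = 5, markers_per_chr = 21,
                                spacing_cM = 5, mb_per_cM = 2) {
  stopifnot(n_chr >= 1, markers_per_chr >= 1, spacing_cM > 0)
  chr <- rep(as.character(seq_len(n_chr)), each = markers_per_chr)
  pos <- rep(seq(0, by = spacing_cM, length.out = markers_per_chr), n_chr)
  marker <- sprintf("rs%s_%03d", chr, rep(seq_len(markers_per_chr), n_chr))
  founder_map(marker, chr, cM = pos, Mb = pos * mb_per_cM)
}

#' Simulation configuration with planted ground truth
#'
#' Bundles the knobs of the synthetic world: panel size, replicate count,
#' planted QTL effects, strain-mean heritability and the causal (MR) slope.
#'
#' @param n_strains number of RI strains (>= 2).
#' @param n_animals_per_strain replicate animals per strain (default 8,
#'   i.e. at least 4 per sex).
#' @param qtl `data.frame` with columns `chr`, `Mb`, `effect` giving planted
#'   additive allele effects in trait units, or `NULL` for a pure-noise trait.
#' @param h2 fraction of strain-mean variance explained by the planted QTL,
#'   in `[0, 1]`.
#' @param sd_within within-strain (replicate) standard deviation.
#' @param theta causal exposure-to-outcome slope used by
#'   [simulate_mr_statistics()].
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_strains = 60, n_animals_per_strain = 8, qtl = NULL,
                       h2 = 0.5, sd_within = 1, theta = 0.5, seed = NULL) {
  if (n_strains < 2) stop("n_strains must be >= 2")
  if (!is.null(qtl)) {
    stopifnot(is.data.frame(qtl), all(c("chr", "Mb", "effect") %in% names(qtl)))
    if (any(!is.finite(qtl$effect))) stop("QTL effect sizes must be finite")
  }
  if (!is.numeric(h2) || length(h2) != 1L || is.na(h2) || h2 < 0 || h2 > 1)
    stop("h2 must lie in [0, 1]")
  if (sd_within < 0) stop("sd_within must be non-negative")
  structure(list(n_strains = as.integer(n_strains),
                 n_animals_per_strain = as.integer(n_animals_per_strain),
                 qtl = qtl, h2 = h2, sd_within = sd_within,
                 theta = theta, seed = seed),
            class = "sim_config")
}
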