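# fixtures built in code; no binary data anywhere

# minimal single-chromosome panel with a fully informative marker layout
tiny_geno <- function(geno_vec, strains = paste0("s", seq_along(geno_vec)),
                      marker = "m1") {
  fm <- founder_map(marker, "1", 0, 1)
  genotype_matrix(matrix(geno_vec, ncol = 1,
                         dimnames = list(strains, marker)), fm)
}

# survival records: deaths at given days, censored animals at day 10
surv_records <- function(strain, deaths = integer(0), censored = 0) {
  n <- length(deaths) + censored
  data.frame(strain = strain,
             animal_id = paste0(strain, "_", seq_len(n)),
             survival_day = c(deaths, rep(10, censored)),
             status = c(rep(1L, length(deaths)), rep(0L, censored)),
             stringsAsFactors = FALSE)
}

# body-weight records for one animal across days
bw_records <- function(strain, animal, days, weights) {
  data.frame(strain = strain, animal_id = animal, day = days,
             body_weight = weights, stringsAsFactors = FALSE)
}

# long echo records from paired (baseline, day5) values
echo_records <- function(strain, trait, pairs) {
  n <- nrow(pairs)
  data.frame(strain = strain,
             animal_id = rep(paste0(strain, "_", seq_len(n)), 2),
             day = rep(c(-1, 5), each = n),
             trait = trait,
             value = c(pairs[, 1], pairs[, 2]),
             stringsAsFactors = FALSE)
}

# independent OLS oracle for the HK scan: per-marker lm() fit
hk_oracle_lrs <- function(G, y) {
  vapply(seq_len(ncol(G)), function(j) {
    g <- G[, j]
    ok <- !is.na(g)
    if (stats::var(g[ok]) == 0) return(0)
    fit <- stats::lm(y[ok] ~ g[ok])
    rss1 <- sum(stats::resid(fit)^2)
    rss0 <- sum((y[ok] - mean(y[ok]))^2)
    sum(ok) * log(rss0 / rss1)
  }, 0)
}

bundled_evidence <- function(which = c("bwloss", "echo")) {
  which <- match.arg(which)
  f <- if (which == "bwloss") "evidence_bwloss_chr19.tsv"
       else "evidence_echo_chr14.tsv"
  read_evidence(system.file("extdata", f, package = "ritox"))
}
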