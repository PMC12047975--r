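#' Run the full cardiotoxicity systems-genetics pipeline
#'
#' Ties the stages together: simulate (or load) genotypes and per-animal
#' phenotypes, aggregate strain traits, scan the genome, extract the
#' support interval on the peak chromosome, score candidate genes,
#' run two-sample MR, and optionally enrichment. All outputs are plain
#' TSV/JSON; a manifest records seeds and parameters so a rerun with the
#' same config reproduces byte-identical files.
#'
#' @param config list (or path to a JSON file) with optional elements:
#'   `seed` (default 1); `sim` (passed to [sim_config()], plus `map`
#'   arguments for [default_founder_map()]) or `geno`/`pheno` file paths;
#'   `trait` name; `method` ("hk" or "lmm"); `n_perm`; `alpha`; `drop`
#'   (LOD); `evidence` path (default: bundled chromosome-19 body-weight
#'   evidence table); `score` (weights/thresholds); `mr` (either
#'   `exposure`/`outcome` paths or simulation arguments for
#'   [simulate_mr_statistics()]); `enrich` (list with `gene_list`,
#'   `categories` or `gmt`, `background`).
#' @param out_dir output directory (created if needed).
#' @return invisible list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  trait_name <- config$trait %||% "sim_trait"
  method <- config$method %||% "hk"
  n_perm <- config$n_perm %||% 1000L
  alpha <- config$alpha %||% 0.05
  drop <- config$drop %||% 2

  # --- genotypes + phenotypes -------------------------------------------
  if (!is.null(config$geno)) {
    geno <- read_geno_tsv(config$geno)
    pheno <- read_tsv_table(config$pheno)
  } else {
    sim <- config$sim %||% list()
    map <- default_founder_map(n_chr = sim$n_chr %||% 5,
                               markers_per_chr = sim$markers_per_chr %||% 21,
                               spacing_cM = sim$spacing_cM %||% 5)
    qtl <- if (!is.null(sim$qtl)) as.data.frame(sim$qtl)
           else data.frame(chr = "1", Mb = 100, effect = 1)
    cfg <- sim_config(n_strains = sim$n_strains %||% 60,
                      n_animals_per_strain = sim$n_animals_per_strain %||% 8,
                      qtl = qtl, h2 = sim$h2 %||% 0.5,
                      sd_within = sim$sd_within %||% 1,
                      seed = seed)
    geno <- simulate_ri_genotypes(map, cfg$n_strains, seed = seed)
    pheno <- simulate_strain_phenotypes(geno, cfg, trait_name = trait_name)
    write_geno_tsv(geno, file.path(out_dir, "geno.tsv"))
    write_tsv_table(pheno, file.path(out_dir, "phenotypes.tsv"))
  }

  # --- strain traits + scan ---------------------------------------------
  traits <- strain_trait_table(pheno)
  write_tsv_table(traits, file.path(out_dir, "strain_traits.tsv"))
  y <- trait_vector(traits, trait_name)
  scan <- if (method == "lmm") lmm_scan(geno, y) else hk_scan(geno, y)
  thr <- permutation_threshold(geno, y, n_perm = n_perm, alpha = alpha,
                               seed = seed + 1L)
  write_tsv_table(as.data.frame(scan),
                  file.path(out_dir, paste0("scan_", trait_name, ".tsv")))
  peak_chr <- scan$chr[which.max(scan$LOD)]
  interval <- support_interval(scan, peak_chr, drop = drop)
  jsonlite::write_json(
    c(unclass(interval),
      list(lrs_threshold = as.numeric(thr), alpha = alpha,
           peak_significant = max(scan$LRS[is.finite(scan$LRS)]) > thr)),
    file.path(out_dir, "interval.json"), auto_unbox = TRUE, digits = NA)

  # --- candidate scoring -------------------------------------------------
  ev_path <- config$evidence %||%
    system.file("extdata", "evidence_bwloss_chr19.tsv", package = "ritox")
  scores <- NULL
  if (nzchar(ev_path)) {
    sc_cfg <- config$score %||% list()
    scores <- rank_candidates(score_genes(
      read_evidence(ev_path),
      tpm_threshold = sc_cfg$tpm_threshold %||% 2,
      select_frac = sc_cfg$select_frac %||% 0.30))
    write_tsv_table(as.data.frame(scores),
                    file.path(out_dir, "scorecard.tsv"))
  }

  # --- Mendelian randomization ------------------------------------------
  mr_cfg <- config$mr %||% list()
  if (!is.null(mr_cfg$exposure)) {
    exposure <- read_tsv_table(mr_cfg$exposure)
    outcome <- read_tsv_table(mr_cfg$outcome)
  } else {
    sim_mr <- simulate_mr_statistics(
      n_genes = mr_cfg$n_genes %||% 20,
      n_instruments_per_gene = mr_cfg$n_instruments %||% 2,
      theta = mr_cfg$theta %||% 0.5, seed = seed + 2L)
    exposure <- sim_mr$exposure; outcome <- sim_mr$outcome
    write_tsv_table(exposure, file.path(out_dir, "mr_exposure.tsv"))
    write_tsv_table(outcome, file.path(out_dir, "mr_outcome.tsv"))
  }
  mr_res <- run_mr(exposure, outcome, alpha = mr_cfg$alpha %||% 0.05)
  write_tsv_table(as.data.frame(mr_res),
                  file.path(out_dir, "mr_results.tsv"))
  jsonlite::write_json(attr(mr_res, "summary"),
                       file.path(out_dir, "mr_summary.json"),
                       auto_unbox = TRUE, digits = NA)

  # --- enrichment (optional) --------------------------------------------
  enr <- NULL
  if (!is.null(config$enrich)) {
    e <- config$enrich
    cats <- if (!is.null(e$gmt)) read_gmt(e$gmt) else e$categories
    enr <- ora(e$gene_list, cats, e$background,
               min_overlap = e$min_overlap %||% 5, fdr = e$fdr %||% 0.05)
    write_tsv_table(enr, file.path(out_dir, "enrichment.tsv"))
  }

  manifest <- list(package = "ritox",
                   version = as.character(utils::packageVersion("ritox")),
                   seed = seed, trait = trait_name, method = method,
                   n_perm = n_perm, alpha = alpha, drop = drop,
                   lrs_threshold = as.numeric(thr),
                   peak = list(chr = interval$chr, Mb = interval$peak_Mb,
                               marker = interval$peak_marker))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(geno = geno, pheno = pheno, traits = traits, scan = scan,
                 threshold = thr, interval = interval, scores = scores,
                 mr = mr_res, enrichment = enr, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
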