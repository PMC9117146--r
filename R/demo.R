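.write_table_with_provenance <- function(df, path, params = list()) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(sprintf("# siftseq %s | %s",
                     as.character(packageVersion("siftseq")),
                     paste(sprintf("%s=%s", names(params),
                                   vapply(params, function(p)
                                     paste(format(p), collapse = ","),
                                     character(1))),
                           collapse = " ")), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' End-to-end demonstration run on generated data
#'
#' Generates a synthetic SIFT-seq experiment with one planted reactive
#' clonotype and runs the full pipeline on it: quality control, the
#' clonotype reactivity fit, TCR retrieval and per-clonotype differential
#' expression for the top candidate, plus the companion procedures on their
#' own simulated inputs (qPCR hit-well screen, substitution-scan motif
#' derivation with a proteome scan, mutation-cohort clonality, HLA LOH).
#' All result tables are written under `out_dir` with a provenance header
#' (package version, resolved parameters); the run is bit-reproducible for a
#' fixed seed.
#'
#' @param seed integer seed driving every stage.
#' @param out_dir output directory (created; default a fresh tempdir
#'   subdirectory).
#' @param config a [sim_config()] for the single-cell stage; the seed is
#'   overridden by `seed`.
#' @return Invisibly, a list with the fitted objects and `out_dir`.
#' @export
run_demo <- function(seed = 1,
                     out_dir = file.path(tempdir(),
                                         sprintf("sift_demo_seed%d", seed)),
                     config = sim_config()) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  config$seed <- seed

  sim <- simulate_sc_experiment(config)
  fit <- sift(sim$matrix, sim$vdj)
  .write_table_with_provenance(fit$responses,
                               file.path(out_dir, "responses.tsv"),
                               fit$params)
  qc <- fit$qc_report
  .write_table_with_provenance(
    data.frame(rule = c("genes_min_cells", names(qc$removed), "retained"),
               count = c(qc$genes_removed, unname(qc$removed), qc$retained)),
    file.path(out_dir, "qc_report.tsv"))

  cand <- fit$responses[fit$responses$is_candidate, , drop = FALSE]
  de <- NULL
  tcr <- NULL
  if (nrow(cand)) {
    top <- cand$clonotype_id[which.min(cand$p_value)]
    tcr <- retrieve_tcr(fit$vdj, top)
    de <- clonotype_de(fit, clonotype_id = top)
    .write_table_with_provenance(de[de$direction != "none", , drop = FALSE],
                                 file.path(out_dir, "de_flagged.tsv"),
                                 list(clonotype = top))
    .write_table_with_provenance(rbind(tcr$TRA, tcr$TRB),
                                 file.path(out_dir, "tcr_report.tsv"),
                                 list(clonotype = top))
  }

  qp <- simulate_qpcr_plate(n_wells = 24, hit_wells = 7, hit_delta = 4,
                            noise_sd = 0.3, seed = seed + 1)
  hits <- call_hit_wells(compute_delta_ct(qp$plate))
  .write_table_with_provenance(hits, file.path(out_dir, "qpcr_hits.tsv"))

  sc <- simulate_scan_table("xxxxGWTTK", "ALHGGWTTK", seed = seed + 2)
  motif <- derive_motif(sc$scan)
  proteome <- structure(
    c(PIK3CA_WT = "MSAHHGGWTTKMDWIFHTIKQHALN",
      PIK3CA_MUT = "MSALHGGWTTKMDWIFHTIKQHALN",
      DECOY1 = "MKTWQRPLANNGGWTSKVALIDE",
      DECOY2 = "MGASNDKLHWTTKPPLV"),
    class = "protein_set")
  matches <- scan_proteins(motif, proteome)
  .write_table_with_provenance(matches, file.path(out_dir, "motif_matches.tsv"),
                               list(motif = format_motif(motif)))

  mc <- simulate_mutation_cohort(seed = seed + 3)
  clon <- ccf_calls(mc$mutations)
  .write_table_with_provenance(
    clon[, c("sample_id", "vaf", "ccf", "ci_low", "ci_high", "clonality")],
    file.path(out_dir, "clonality.tsv"))

  hla <- simulate_hla_sites(seed = seed + 4)
  loh <- call_hla_loh(hla$sites)
  .write_table_with_provenance(
    data.frame(allele = names(loh$allele_cn_median),
               median_cn = unname(loh$allele_cn_median),
               imbalance_p = loh$imbalance_p, is_loh = loh$is_loh,
               lost_allele = loh$lost_allele),
    file.path(out_dir, "hla_loh.tsv"))

  summary_lines <- c(
    sprintf("planted reactive clonotype: %s",
            paste(sim$truth$reactive_ids, collapse = ",")),
    sprintf("candidates: %s",
            if (nrow(cand)) paste(cand$clonotype_id, collapse = ",")
            else "(none)"),
    sprintf("qPCR hits: %s",
            paste(hits$well_id[hits$is_hit], collapse = ",")),
    sprintf("derived motif: %s", format_motif(motif, dashed = TRUE)),
    sprintf("clonal fraction: %.3f", mean(clon$clonality == "CLONAL")),
    sprintf("HLA LOH: %s (lost %s)", loh$is_loh, loh$lost_allele))
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))

  invisible(list(fit = fit, truth = sim$truth, hits = hits, motif = motif,
                 motif_matches = matches, clonality = clon, loh = loh,
                 de = de, tcr = tcr, out_dir = out_dir))
}
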