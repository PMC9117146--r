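#' Configuration for the synthetic SIFT-seq experiment generator
#'
#' Collects every knob of [simulate_sc_experiment()] with defaults chosen to
#' emulate a screen-positive hit well: a clonotype-structured T cell pool
#' split into matched MUT- and WT-stimulated aliquots, one reactive clonotype
#' that upregulates IFNG and companion activation genes under MUT only, and
#' optional planted quality-control violations.
#'
#' @param seed integer seed fixing all draws (`NULL` = use current RNG state).
#' @param n_genes total number of genes, including the named immune genes
#'   (IFNG, TNF, IL2, XCL1, CD3E, CD4, CD8A) and 13 mitochondrial `MT-` genes.
#' @param n_cells_per_condition cells per stimulation aliquot.
#' @param n_clonotypes number of distinct TCR clonotypes.
#' @param clonotype_zipf_exponent exponent `s` of the Zipf law used for
#'   clonotype sizes (P(clonotype k) proportional to k^-s). Post-stimulation
#'   repertoires are strongly skewed; 1.5 gives one dominant clone plus a
#'   tail, as seen in hit wells.
#' @param reactive_clonotypes list of `list(clonotype_id=, effect_fold=,
#'   activation_genes=)` entries; `effect_fold` (>= 1) multiplies the mean of
#'   IFNG and the activation set in MUT-condition cells of that clonotype.
#' @param lineage_assignment optional named character vector mapping
#'   clonotype ids to `"CD8"`/`"CD4"`; unassigned clonotypes are drawn
#'   CD8-skewed (65/35).
#' @param doublet_rate,high_mito_rate,low_gene_rate,multi_chain_rate,no_vdj_rate
#'   fractions in \[0,1\] of cells planted with each QC violation (doublet =
#'   summed pair of cells; high-mito = mitochondrial fraction resampled above
#'   0.15; low-gene = thinned below 200 detected genes; multi-chain = 3 TRA
#'   contigs; no-vdj = contigs withheld). Violation sets are disjoint.
#' @param nb_dispersion negative-binomial dispersion phi (variance
#'   mu + phi mu^2).
#' @param mean_library_size target mean UMI per cell.
#' @param gene_mean_shape gamma shape for the unnamed genes' mean profile;
#'   small values give realistic highly-skewed expression.
#' @param mito_baseline baseline fraction of library mass on MT- genes.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = NULL,
                       n_genes = 1000,
                       n_cells_per_condition = 50,
                       n_clonotypes = 20,
                       clonotype_zipf_exponent = 1.5,
                       reactive_clonotypes = list(list(
                         clonotype_id = "clonotype1",
                         effect_fold = 8,
                         activation_genes = c("IFNG", "TNF", "IL2", "XCL1"))),
                       lineage_assignment = NULL,
                       doublet_rate = 0,
                       high_mito_rate = 0,
                       low_gene_rate = 0,
                       multi_chain_rate = 0,
                       no_vdj_rate = 0,
                       nb_dispersion = 0.5,
                       mean_library_size = 2000,
                       gene_mean_shape = 0.3,
                       mito_baseline = 0.08) {
  rates <- c(doublet_rate, high_mito_rate, low_gene_rate, multi_chain_rate,
             no_vdj_rate)
  if (any(rates < 0 | rates > 1)) stop("violation rates must be in [0, 1]")
  if (sum(rates) > 1) stop("violation rates must sum to at most 1")
  for (rc in reactive_clonotypes)
    if (rc$effect_fold < 1) stop("effect_fold must be >= 1")
  if (clonotype_zipf_exponent <= 0) stop("zipf exponent must be positive")
  if (n_genes < 25) stop("n_genes must accommodate the named genes")
  if (n_clonotypes > 2 * n_cells_per_condition)
    stop("more clonotypes than cells")
  structure(list(
    seed = seed, n_genes = n_genes,
    n_cells_per_condition = n_cells_per_condition,
    n_clonotypes = n_clonotypes,
    clonotype_zipf_exponent = clonotype_zipf_exponent,
    reactive_clonotypes = reactive_clonotypes,
    lineage_assignment = lineage_assignment,
    doublet_rate = doublet_rate, high_mito_rate = high_mito_rate,
    low_gene_rate = low_gene_rate, multi_chain_rate = multi_chain_rate,
    no_vdj_rate = no_vdj_rate, nb_dispersion = nb_dispersion,
    mean_library_size = mean_library_size,
    gene_mean_shape = gene_mean_shape, mito_baseline = mito_baseline),
    class = "sim_config")
}

.mt_gene_names <- c("MT-ND1", "MT-ND2", "MT-CO1", "MT-CO2", "MT-ATP8",
                    "MT-ATP6", "MT-CO3", "MT-ND3", "MT-ND4L", "MT-ND4",
                    "MT-ND5", "MT-ND6", "MT-CYB")
.named_immune_genes <- c("IFNG", "TNF", "IL2", "XCL1", "CD3E", "CD4", "CD8A")

.random_barcodes <- function(n) {
  bc <- replicate(n, paste0(paste(sample(c("A", "C", "G", "T"), 16,
                                         replace = TRUE), collapse = ""),
                            "-1"))
  while (anyDuplicated(bc)) {
    dup <- which(duplicated(bc))
    bc[dup] <- replicate(length(dup), paste0(
      paste(sample(c("A", "C", "G", "T"), 16, replace = TRUE),
            collapse = ""), "-1"))
  }
  bc
}

.random_cdr3 <- function(len, anchor_start = "C", anchor_end = "F") {
  aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  paste0(anchor_start,
         paste(sample(aa, len - 2, replace = TRUE), collapse = ""),
         anchor_end)
}

.random_nt <- function(aa_len) {
  paste(sample(c("A", "C", "G", "T"), 3 * aa_len, replace = TRUE),
        collapse = "")
}

#' Simulate a paired MUT/WT single-cell SIFT-seq experiment
#'
#' Generates a genes x cells UMI count matrix for the two stimulation
#' aliquots, a matching V(D)J contig table, and a ground-truth table.
#' Clonotype sizes follow a Zipf law shared between conditions; baseline
#' counts are negative-binomial with gamma-distributed gene means; reactive
#' clonotypes have the means of IFNG and their activation gene set multiplied
#' by `effect_fold` in MUT cells only; each clonotype carries a CD8 or CD4
#' lineage program (CD8A high/CD4 low or vice versa, CD3E high throughout).
#' QC violations are planted exactly at the configured counts
#' (`round(rate * n_cells)`) on disjoint cell sets.
#'
#' @param config a [sim_config()].
#' @return A list with elements `matrix` (an [expr_matrix()] with condition
#'   labels), `vdj` (a `vdj_table`) and `truth` (list with per-cell
#'   data.frame `cells`, `reactive_ids`, `clonotype_chains`).
#' @export
simulate_sc_experiment <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n_cond <- config$n_cells_per_condition
  n_cells <- 2 * n_cond
  K <- config$n_clonotypes

  gene_names <- c(.named_immune_genes, .mt_gene_names,
                  sprintf("GENE%04d", seq_len(config$n_genes -
                                                length(.named_immune_genes) -
                                                length(.mt_gene_names))))
  n_genes <- length(gene_names)

  # baseline gene means: fixed immune means, MT- genes at mito_baseline mass,
  # remaining mass spread over unnamed genes with a gamma profile
  lib <- config$mean_library_size
  base_mean <- numeric(n_genes)
  names(base_mean) <- gene_names
  base_mean["IFNG"] <- 0.5
  base_mean["TNF"] <- 0.5
  base_mean["IL2"] <- 0.3
  base_mean["XCL1"] <- 0.3
  base_mean["CD3E"] <- 3
  mt_idx <- grep("^MT-", gene_names)
  base_mean[mt_idx] <- config$mito_baseline * lib / length(mt_idx)
  other_idx <- which(base_mean == 0 & !(gene_names %in% c("CD4", "CD8A")))
  w <- rgamma(length(other_idx), shape = config$gene_mean_shape, rate = 1)
  remaining <- lib * (1 - config$mito_baseline) -
    sum(base_mean[c("IFNG", "TNF", "IL2", "XCL1", "CD3E")]) - 2.05
  base_mean[other_idx] <- remaining * w / sum(w)

  # clonotype structure shared between conditions
  zipf_p <- (seq_len(K))^(-config$clonotype_zipf_exponent)
  zipf_p <- zipf_p / sum(zipf_p)
  clono_ids <- sprintf("clonotype%d", seq_len(K))
  cell_clono <- sample(clono_ids, n_cells, replace = TRUE, prob = zipf_p)
  condition <- rep(c("MUT", "WT"), each = n_cond)
  barcodes <- .random_barcodes(n_cells)

  reactive_ids <- vapply(config$reactive_clonotypes, `[[`, character(1),
                         "clonotype_id")

  # reactive clonotypes are CD8 (HLA-I restricted) unless explicitly assigned
  lineage <- config$lineage_assignment
  drawn <- setNames(sample(c("CD8", "CD4"), K, replace = TRUE,
                           prob = c(0.65, 0.35)), clono_ids)
  drawn[intersect(reactive_ids, clono_ids)] <- "CD8"
  if (!is.null(lineage)) drawn[names(lineage)] <- lineage
  lineage <- drawn

  # per-cell mean matrix
  mu <- matrix(base_mean, nrow = n_genes, ncol = n_cells,
               dimnames = list(gene_names, barcodes))
  is_cd8 <- lineage[cell_clono] == "CD8"
  mu["CD8A", ] <- ifelse(is_cd8, 2, 0.05)
  mu["CD4", ] <- ifelse(is_cd8, 0.05, 2)
  for (rc in config$reactive_clonotypes) {
    hit <- cell_clono == rc$clonotype_id & condition == "MUT"
    genes <- unique(c("IFNG", rc$activation_genes))
    genes <- intersect(genes, gene_names)
    mu[genes, hit] <- mu[genes, hit] * rc$effect_fold
  }

  size <- 1 / config$nb_dispersion
  counts <- matrix(rnbinom(n_genes * n_cells, mu = as.vector(mu),
                           size = size),
                   nrow = n_genes, dimnames = dimnames(mu))

  # disjoint planted QC violations
  k <- vapply(c("doublet_rate", "high_mito_rate", "low_gene_rate",
                "multi_chain_rate", "no_vdj_rate"),
              function(f) round(config[[f]] * n_cells), numeric(1))
  viol_cells <- sample(n_cells, sum(k))
  groups <- rep(names(k), times = k)
  idx_doublet <- viol_cells[groups == "doublet_rate"]
  idx_mito <- viol_cells[groups == "high_mito_rate"]
  idx_lowgene <- viol_cells[groups == "low_gene_rate"]
  idx_multi <- viol_cells[groups == "multi_chain_rate"]
  idx_novdj <- viol_cells[groups == "no_vdj_rate"]

  clean <- setdiff(seq_len(n_cells), viol_cells)
  if (length(idx_doublet)) {
    partners <- sample(clean, length(idx_doublet), replace = TRUE)
    counts[, idx_doublet] <- counts[, idx_doublet, drop = FALSE] +
      counts[, partners, drop = FALSE]
  }
  for (i in idx_mito) {
    non_mt <- sum(counts[-mt_idx, i])
    f <- runif(1, 0.25, 0.4)
    target_mt <- ceiling(f / (1 - f) * max(non_mt, 1))
    counts[mt_idx, i] <- as.vector(rmultinom(1, target_mt,
                                             rep(1, length(mt_idx))))
  }
  for (i in idx_lowgene) {
    nz <- setdiff(which(counts[, i] > 0), mt_idx)
    keep <- if (length(nz) > 120) sample(nz, 120) else nz
    drop <- setdiff(seq_len(n_genes), keep)
    counts[drop, i] <- 0
  }

  # V(D)J contigs: one consensus TRA/TRB pair per clonotype
  v_tra <- sprintf("TRAV%d-%d", sample(1:38, K, TRUE), sample(1:2, K, TRUE))
  j_tra <- sprintf("TRAJ%d", sample(1:58, K, TRUE))
  v_trb <- sprintf("TRBV%d-%d", sample(1:30, K, TRUE), sample(1:3, K, TRUE))
  j_trb <- sprintf("TRBJ%d-%d", sample(1:2, K, TRUE), sample(1:7, K, TRUE))
  chains <- data.frame(
    clonotype_id = clono_ids,
    tra_v = v_tra, tra_j = j_tra,
    tra_cdr3 = vapply(sample(12:15, K, TRUE), .random_cdr3, character(1)),
    trb_v = v_trb, trb_j = j_trb,
    trb_cdr3 = vapply(sample(13:19, K, TRUE), .random_cdr3, character(1)),
    stringsAsFactors = FALSE)
  chains$tra_nt <- vapply(nchar(chains$tra_cdr3), .random_nt, character(1))
  chains$trb_nt <- vapply(nchar(chains$trb_cdr3), .random_nt, character(1))

  vdj_rows <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    if (i %in% idx_novdj) next
    ch <- chains[chains$clonotype_id == cell_clono[i], ]
    rows <- data.frame(
      barcode = barcodes[i],
      chain = c("TRA", "TRB"),
      v_gene = c(ch$tra_v, ch$trb_v),
      j_gene = c(ch$tra_j, ch$trb_j),
      cdr3_aa = c(ch$tra_cdr3, ch$trb_cdr3),
      cdr3_nt = c(ch$tra_nt, ch$trb_nt),
      clonotype_id = ch$clonotype_id,
      stringsAsFactors = FALSE)
    if (i %in% idx_multi) {
      extra <- rows[c(1, 1), ]
      extra$cdr3_aa <- vapply(nchar(extra$cdr3_aa), .random_cdr3,
                              character(1))
      extra$cdr3_nt <- vapply(nchar(extra$cdr3_aa), .random_nt, character(1))
      rows <- rbind(rows, extra)
    }
    vdj_rows[[i]] <- rows
  }
  vdj <- do.call(rbind, vdj_rows)
  rownames(vdj) <- NULL
  class(vdj) <- c("vdj_table", "data.frame")

  truth_cells <- data.frame(
    barcode = barcodes,
    condition = condition,
    clonotype_id = cell_clono,
    lineage = unname(lineage[cell_clono]),
    is_doublet = seq_len(n_cells) %in% idx_doublet,
    is_high_mito = seq_len(n_cells) %in% idx_mito,
    is_low_gene = seq_len(n_cells) %in% idx_lowgene,
    is_multi_chain = seq_len(n_cells) %in% idx_multi,
    has_vdj = !(seq_len(n_cells) %in% idx_novdj),
    stringsAsFactors = FALSE)

  list(matrix = expr_matrix(counts, condition = condition),
       vdj = vdj,
       truth = list(cells = truth_cells,
                    reactive_ids = reactive_ids,
                    lineage = lineage,
                    clonotype_chains = chains))
}

#' Simulate a qPCR screening plate
#'
#' Non-hit wells draw delta-Ct ~ Normal(0, `noise_sd`); hit wells draw
#' delta-Ct ~ Normal(`hit_delta`, `noise_sd`). Ct pairs are emitted around a
#' baseline cycle so that `ct_wt - ct_mut` equals the drawn delta-Ct.
#'
#' @param n_wells number of wells.
#' @param hit_wells well ids (e.g. `"W07"`) or integer indices of planted
#'   hits.
#' @param hit_delta mean delta-Ct of hit wells, cycles (> 0).
#' @param noise_sd standard deviation of well-level noise, cycles.
#' @param seed integer seed or `NULL`.
#' @param baseline_ct mean Ct about which pairs are centred.
#' @return A list with `plate` (data.frame of class `qpcr_plate`: `well_id`,
#'   `ct_mut`, `ct_wt`) and `truth` (logical `is_hit` per well plus the drawn
#'   delta-Ct).
#' @export
simulate_qpcr_plate <- function(n_wells = 24, hit_wells = integer(0),
                                hit_delta = 4, noise_sd = 0.3, seed = NULL,
                                baseline_ct = 26) {
  if (hit_delta <= 0) stop("hit_delta must be positive")
  if (!is.null(seed)) set.seed(seed)
  well_id <- sprintf("W%02d", seq_len(n_wells))
  is_hit <- if (is.numeric(hit_wells)) seq_len(n_wells) %in% hit_wells
            else well_id %in% hit_wells
  delta <- rnorm(n_wells, mean = ifelse(is_hit, hit_delta, 0), sd = noise_sd)
  plate <- data.frame(well_id = well_id,
                      ct_mut = baseline_ct - delta / 2,
                      ct_wt = baseline_ct + delta / 2,
                      stringsAsFactors = FALSE)
  class(plate) <- c("qpcr_plate", "data.frame")
  list(plate = plate,
       truth = data.frame(well_id = well_id, is_hit = is_hit,
                          delta_ct = delta, stringsAsFactors = FALSE))
}

#' Simulate an alanine/glycine substitution-scan response table
#'
#' Emulates a TCR fine-specificity scan against a known recognition motif:
#' substitutions at fixed (TCR-contact) positions abolish function (response
#' below `floor` for every amenable substitution), while substitutions at
#' wildcard positions retain detectable function (response at least
#' `2 * floor` for at least one amenable substitution). Positions whose
#' native residue equals the substituted residue are marked not amenable
#' (response `NA`).
#'
#' @param true_motif motif string, e.g. `"xxxxGWTTK"` or
#'   `"x-x-x-x-G-W-T-T-K"`; fixed positions must match the native peptide.
#' @param native_peptide the native peptide sequence (same length).
#' @param floor detectability floor on the fraction-of-maximum scale.
#' @param noise_sd response noise standard deviation.
#' @param seed integer seed or `NULL`.
#' @return A list with `scan` (data.frame of class `scan_table`: `position`,
#'   `substitution`, `response`, `amenable`, with the native peptide as the
#'   `"native_peptide"` attribute) and `truth` (the generating motif).
#' @export
simulate_scan_table <- function(true_motif, native_peptide, floor = 0.10,
                                noise_sd = 0.03, seed = NULL) {
  motif <- parse_motif(true_motif)
  pep <- strsplit(toupper(native_peptide), "")[[1]]
  pat <- strsplit(motif$pattern, "")[[1]]
  if (length(pat) != length(pep))
    stop("motif length must equal peptide length")
  if (any(pat != "x" & pat != pep))
    stop("fixed motif positions must equal the native residue")
  if (!is.null(seed)) set.seed(seed)
  sub_res <- c(ALA = "A", GLY = "G")
  rows <- list()
  for (p in seq_along(pep)) {
    amen <- pep[p] != sub_res
    resp <- rep(NA_real_, 2)
    if (pat[p] == "x") {
      first <- which(amen)[1]
      for (s in which(amen)) {
        r <- if (s == first) max(rnorm(1, 0.8, noise_sd), 2 * floor)
             else min(max(rnorm(1, 0.5, noise_sd), 0), 1.2)
        resp[s] <- r
      }
    } else {
      resp[amen] <- pmin(abs(rnorm(sum(amen), 0, noise_sd)), 0.99 * floor)
    }
    rows[[p]] <- data.frame(position = p, substitution = names(sub_res),
                            response = resp, amenable = amen,
                            stringsAsFactors = FALSE)
  }
  scan <- do.call(rbind, rows)
  rownames(scan) <- NULL
  attr(scan, "native_peptide") <- paste(pep, collapse = "")
  class(scan) <- c("scan_table", "data.frame")
  list(scan = scan, truth = motif)
}

#' Simulate a hotspot-mutation cohort with known clonality
#'
#' Each record draws a true cancer cell fraction (clonal: 1.0; subclonal:
#' Uniform(0.1, 0.7)), a tumor purity, integer copy numbers and a
#' mutant-allele multiplicity, then samples alt reads binomially at the
#' expected variant allele fraction
#' `CCF * m * purity / (purity * CN_t + (1 - purity) * 2)`.
#'
#' @param n number of records.
#' @param clonal_fraction fraction of truly clonal records. The default is
#'   the clonal prevalence observed for PIK3CA H1047L in a 131-patient
#'   pan-cancer cohort (102/131).
#' @param depth_mean mean sequencing depth (> 0).
#' @param purity_range range of tumor purity, Uniform.
#' @param seed integer seed or `NULL`.
#' @return A list with `mutations` (data.frame of class `mutation_table`) and
#'   `truth` (`true_ccf`, `is_clonal` per record).
#' @export
simulate_mutation_cohort <- function(n = 131, clonal_fraction = 102 / 131,
                                     depth_mean = 500,
                                     purity_range = c(0.2, 0.9),
                                     seed = NULL) {
  if (clonal_fraction < 0 || clonal_fraction > 1)
    stop("clonal_fraction must be in [0, 1]")
  if (depth_mean <= 0) stop("depth_mean must be positive")
  if (!is.null(seed)) set.seed(seed)
  is_clonal <- runif(n) < clonal_fraction
  ccf <- ifelse(is_clonal, 1, runif(n, 0.1, 0.7))
  purity <- runif(n, purity_range[1], purity_range[2])
  cn_tumor <- sample(2:4, n, replace = TRUE, prob = c(0.6, 0.25, 0.15))
  cn_major <- ceiling(cn_tumor / 2)
  m <- vapply(cn_major, function(cm) sample.int(cm, 1), integer(1))
  depth <- pmax(rpois(n, depth_mean), 20L)
  vaf_exp <- ccf * m * purity / (purity * cn_tumor + (1 - purity) * 2)
  alt <- rbinom(n, depth, vaf_exp)
  muts <- data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    gene = "PIK3CA", protein_change = "H1047L",
    alt_reads = alt, ref_reads = depth - alt,
    purity = purity, cn_tumor = cn_tumor, cn_normal = 2L, m = m,
    site_class = sample(c("PRIMARY", "METASTASIS"), n, replace = TRUE),
    stringsAsFactors = FALSE)
  class(muts) <- c("mutation_table", "data.frame")
  list(mutations = muts,
       truth = data.frame(sample_id = muts$sample_id, true_ccf = ccf,
                          is_clonal = is_clonal, stringsAsFactors = FALSE))
}

#' Simulate HLA-A mismatch-site allele coverage
#'
#' Emits per-site read counts for the two HLA-A alleles in a matched
#' normal/tumor pair. The normal sample is balanced (Binomial(cov, 0.5) per
#' site). Under loss of heterozygosity the tumor's lost-allele expected read
#' fraction is `(1 - purity) / ((1 - purity) * 2 + purity)`, i.e. the
#' contamination-only fraction when tumor cells retain a single copy of the
#' other allele; otherwise the tumor is balanced too.
#'
#' @param n_sites number of mismatched positions (>= 5).
#' @param loh logical; plant an allelic loss?
#' @param purity tumor purity in (0, 1\].
#' @param coverage_mean mean site coverage (Poisson).
#' @param seed integer seed or `NULL`.
#' @param lost_allele which allele is lost when `loh` (`"A2"` default).
#' @return A list with `sites` (long data.frame of class `hla_site_table`:
#'   `site_pos`, `allele`, `reads_tumor`, `reads_normal`; purity stored as an
#'   attribute) and `truth` (`loh`, `lost_allele`).
#' @export
simulate_hla_sites <- function(n_sites = 20, loh = TRUE, purity = 0.6,
                               coverage_mean = 200, seed = NULL,
                               lost_allele = "A2") {
  if (n_sites < 5) stop("need at least 5 mismatch sites")
  if (purity <= 0 || purity > 1) stop("purity must be in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  pos <- sort(sample(1:3500, n_sites))
  cov_n <- pmax(rpois(n_sites, coverage_mean), 10L)
  cov_t <- pmax(rpois(n_sites, coverage_mean), 10L)
  n_a1 <- rbinom(n_sites, cov_n, 0.5)
  frac_lost <- if (loh) (1 - purity) / ((1 - purity) * 2 + purity) else 0.5
  p_a1 <- if (loh && lost_allele == "A1") frac_lost
          else if (loh) 1 - frac_lost else 0.5
  t_a1 <- rbinom(n_sites, cov_t, p_a1)
  sites <- rbind(
    data.frame(site_pos = pos, allele = "A1", reads_tumor = t_a1,
               reads_normal = n_a1, stringsAsFactors = FALSE),
    data.frame(site_pos = pos, allele = "A2", reads_tumor = cov_t - t_a1,
               reads_normal = cov_n - n_a1, stringsAsFactors = FALSE))
  sites <- sites[order(sites$site_pos, sites$allele), ]
  rownames(sites) <- NULL
  attr(sites, "purity") <- purity
  class(sites) <- c("hla_site_table", "data.frame")
  list(sites = sites,
       truth = list(loh = loh, lost_allele = if (loh) lost_allele else NA))
}
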