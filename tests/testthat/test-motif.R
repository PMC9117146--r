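scan_row <- function(position, substitution, response, amenable = TRUE) {
  data.frame(position = position, substitution = substitution,
             response = response, amenable = amenable,
             stringsAsFactors = FALSE)
}

# scan over native ALHGGWTTK: P1-P4 tolerate >= one substitution, P5-P9
# abolish function for every amenable substitution
example_scan <- function() {
  rows <- list()
  for (p in 1:9) {
    for (sub in c("ALA", "GLY")) {
      native <- strsplit("ALHGGWTTK", "")[[1]][p]
      amen <- !(native == "A" && sub == "ALA") &&
              !(native == "G" && sub == "GLY")
      resp <- if (!amen) NA_real_ else if (p <= 4) 0.6 else 0.02
      rows[[length(rows) + 1]] <- scan_row(p, sub, resp, amen)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "native_peptide") <- "ALHGGWTTK"
  out
}

test_that("the printed recognition motif is recovered from the example scan", {
  m <- derive_motif(example_scan())
  expect_equal(format_motif(m), "xxxxGWTTK")
  expect_equal(format_motif(m, dashed = TRUE), "x-x-x-x-G-W-T-T-K")
})

test_that("degenerate scans give all-wildcard or fully fixed motifs", {
  sc <- example_scan()
  sc$response[sc$amenable] <- 1
  expect_equal(format_motif(derive_motif(sc)), "xxxxxxxxx")
  sc$response[sc$amenable] <- 0
  # every position of an Ala/Gly scan has >= 1 amenable substitution, so a
  # fully abolishing scan fixes the whole native peptide
  expect_equal(format_motif(derive_motif(sc)), "ALHGGWTTK")
  expect_error(derive_motif(sc[0, ], native_peptide = "ALHGGWTTK"),
               "empty")
})

test_that("positions with no amenable substitution inherit the configured status", {
  # only an Ala scan is available: the native Ala position is unprobed
  sc <- rbind(scan_row(1, "ALA", NA, amenable = FALSE),
              scan_row(2, "ALA", 0.02), scan_row(3, "ALA", 0.02))
  attr(sc, "native_peptide") <- "AWK"
  expect_equal(format_motif(derive_motif(sc)), "xWK")
  expect_equal(format_motif(derive_motif(sc, inamenable = "fixed")), "AWK")
})

test_that("the two derivation rules differ on partial loss of function", {
  # response 0.4: detectable (>= floor 0.1) but a >= 50% loss
  sc <- rbind(scan_row(1, "ALA", 0.4), scan_row(1, "GLY", 0.02))
  attr(sc, "native_peptide") <- "W"
  expect_equal(format_motif(derive_motif(sc, rule = "any_detectable")), "x")
  expect_equal(format_motif(derive_motif(sc, rule = "half_loss")), "W")
})

test_that("motif scanning matches the peptide pair from the cross-reactivity screen", {
  ps <- structure(c(pMut = "ALHGGWTTK", pWT = "AHHGGWTTK"),
                  class = "protein_set")
  hits <- scan_proteins("x-x-x-x-G-W-T-T-K", ps)
  expect_equal(nrow(hits), 2)
  expect_equal(hits$start, c(1, 1))
  expect_setequal(hits$protein_id, c("pMut", "pWT"))
})

test_that("wildcard-only motifs count windows combinatorially", {
  ps <- structure(setNames(paste(rep("A", 20), collapse = ""), "s"),
                  class = "protein_set")
  hits <- scan_proteins(strrep("x", 9), ps)
  expect_equal(nrow(hits), 12)  # 20 - 9 + 1
  expect_equal(hits$start, 1:12)
})

test_that("sequence ambiguity X never satisfies a fixed position", {
  ps <- structure(c(a = "GWXTK", b = "GWTTK", c = "XWTTK"),
                  class = "protein_set")
  expect_equal(scan_proteins("GWTTK", ps)$protein_id, "b")
  # but X is matched by wildcards
  expect_equal(nrow(scan_proteins("xWTTK", ps)), 2)
})

test_that("overlapping matches are all reported", {
  ps <- structure(c(s = "AAAAA"), class = "protein_set")
  expect_equal(scan_proteins("AA", ps)$start, 1:4)
})

test_that("zero-wildcard motifs match exactly the native windows", {
  set.seed(5)
  ps <- random_protein_set(40, max_len = 60)
  hits <- scan_proteins("GWTTK", ps)
  brute <- oracle_scan_bruteforce("GWTTK", ps)
  expect_equal(nrow(hits), nrow(brute))
  windows <- hits$matched_window
  expect_true(all(windows == "GWTTK"))
})

test_that("scanner agrees with the brute-force window oracle on random input", {
  set.seed(42)
  ps <- random_protein_set(100, max_len = 50)
  for (pattern in c("xxXAK", "xxxxGWTTK", "Cx", "xAx")) {
    hits <- scan_proteins(pattern, ps)
    brute <- oracle_scan_bruteforce(gsub("X", "x", pattern), ps)
    rownames(brute) <- NULL
    expect_equal(hits$protein_id, brute$protein_id)
    expect_equal(hits$start, brute$start)
    expect_equal(hits$matched_window, brute$matched_window)
  }
})

test_that("motif derivation round-trips the scan-table generator", {
  ok <- 0
  for (s in 1:100) {
    sim <- simulate_scan_table("xxxxGWTTK", "ALHGGWTTK", floor = 0.1,
                               noise_sd = 0.1 / 3, seed = s)
    if (format_motif(derive_motif(sim$scan)) == "xxxxGWTTK") ok <- ok + 1
  }
  expect_gte(ok, 99)
  # degenerate motifs round-trip too
  all_wild <- simulate_scan_table("xxxxxxxxx", "ALHGGWTTK", seed = 1)
  expect_equal(format_motif(derive_motif(all_wild$scan)), "xxxxxxxxx")
  all_fixed <- simulate_scan_table("ALHGGWTTK", "ALHGGWTTK", seed = 2)
  expect_equal(format_motif(derive_motif(all_fixed$scan)), "ALHGGWTTK")
})

test_that("motif parsing validates characters and normalizes spellings", {
  expect_equal(parse_motif("x-x-x-x-G-W-T-T-K")$pattern, "xxxxGWTTK")
  expect_equal(parse_motif("XxGW")$pattern, "xxGW")
  expect_error(parse_motif("xx1K"), "invalid motif")
  expect_error(parse_motif(""), "empty")
})
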