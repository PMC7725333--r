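write_lines_tmp <- function(lines, fileext, env = parent.frame()) {
  path <- withr::local_tempfile(fileext = fileext, .local_envir = env)
  writeLines(lines, path)
  path
}

tblout_line <- function(target, query, full, b1d, evalue = 1e-30) {
  sprintf(
    "%-20s %-10s %-20s %-10s %9.2g %6.1f %5.1f %9.2g %6.1f %5.1f %5.1f %3d %3d %3d %3d %3d %3d %3d %s",
    target, "-", query, "-", evalue, full, 0, evalue, b1d, 0, 1, 1, 1, 1, 1, 1, 1, 1, "desc words here"
  )
}

test_that("tblout rows map to hits with best-one-domain scores", {
  path <- write_lines_tmp(c(
    "# comment line",
    tblout_line("WP_000000001.1", "GPE00530", 310.2, 305.0),
    "#"
  ), ".tblout")
  hits <- read_hmmer_table(path, "tblout", genome_id = "G1")
  expect_equal(nrow(hits), 1)
  expect_equal(hits$best1dom_bits, 305.0)
  expect_equal(hits$full_bits, 310.2)
  expect_equal(hits$gpe_id, "GPE00530")
  expect_equal(hits$genome_id, "G1")
})

test_that("comment-only tblout gives an empty hit set", {
  path <- write_lines_tmp(c("# header", "#"), ".tblout")
  expect_equal(nrow(read_hmmer_table(path, "tblout")), 0)
})

test_that("duplicate (protein, profile) rows keep the max best-1-dom score", {
  scores <- c(101.5, 250.0, 88.8, 250.1)
  path <- write_lines_tmp(
    vapply(scores, function(s) tblout_line("WP_1", "GPE00510", s + 1, s), ""),
    ".tblout"
  )
  hits <- read_hmmer_table(path, "tblout")
  expect_equal(nrow(hits), 1)
  expect_equal(hits$best1dom_bits, max(scores)) # brute-force max over rows
})

test_that("domtblout takes the best single-domain score across domain rows", {
  dom_line <- function(target, query, full, dom) {
    paste(c(
      target, "-", "500", query, "-", "400", "1e-50", full, "0.0",
      "1", "2", "1e-20", "1e-20", dom, "0.0", "1", "100", "1", "100", "1", "100", "0.9", "desc"
    ), collapse = " ")
  }
  path <- write_lines_tmp(c(
    dom_line("WP_1", "GPE00510", "300.0", "180.0"),
    dom_line("WP_1", "GPE00510", "300.0", "220.5")
  ), ".domtblout")
  hits <- read_hmmer_table(path, "domtblout")
  expect_equal(hits$best1dom_bits, 220.5)
  expect_equal(hits$full_bits, 300.0)
})

test_that("malformed tables are reported with line numbers and dialects checked", {
  path <- write_lines_tmp(c(tblout_line("WP_1", "GPE00510", 100, 90), "too short row"), ".tblout")
  expect_error(read_hmmer_table(path, "tblout"), "line")
  expect_error(read_hmmer_table(path, "nope"), class = "glyco_input_error")
  expect_error(read_hmmer_table(tempfile(), "tblout"), class = "glyco_input_error")
})

test_that("blast coverage is computed from alignment and query lengths", {
  path <- write_lines_tmp("GPE90010_Q81A42\tWP_9\t44.0\t45.0\t285\t300\t1e-80\t410", ".tsv")
  hits <- read_blast_table(path, genome_id = "G1")
  expect_equal(hits$coverage_pct, 100 * 285 / 300)
  expect_equal(hits$similarity_pct, 45.0)
  expect_equal(hits$gpe_id, "GPE90010")
})

test_that("a declared coverage column is used verbatim", {
  path <- write_lines_tmp("GPE90020\tWP_9\t52.0\t97.5", ".tsv")
  hits <- read_blast_table(path, columns = c("qseqid", "sseqid", "ppos", "qcovs"))
  expect_equal(hits$coverage_pct, 97.5)
  expect_equal(hits$similarity_pct, 52.0)
})

test_that("coverage above 100% clamps with a warning", {
  # alignment longer than query: 330/300 -> 110%, must clamp to 100
  path <- write_lines_tmp("GPE90020\tWP_9\t52.0\t52.0\t330\t300\t1e-10\t100", ".tsv")
  expect_warning(hits <- read_blast_table(path), "clamp")
  expect_equal(hits$coverage_pct, 100)
})

test_that("missing blast columns are named in the error", {
  path <- write_lines_tmp("q\ts\t50", ".tsv")
  err <- expect_error(
    read_blast_table(path, columns = c("qseqid", "sseqid", "pident")),
    class = "glyco_input_error"
  )
  expect_match(conditionMessage(err), "ppos")
  expect_error(
    read_blast_table(path, columns = c("qseqid", "sseqid", "ppos")),
    "qcovs|length",
    class = "glyco_input_error"
  )
})

test_that("HMM thresholds are inclusive at the boundary for every family", {
  reg <- load_registry()
  fams <- reg$enzyme_families[reg$enzyme_families$detection_mode == "hmm_profile", ]
  hits <- dplyr::bind_rows(lapply(seq_len(nrow(fams)), function(i) {
    dplyr::bind_rows(
      hmm_hit(fams$gpe_id[i], fams$threshold_bits[i], protein = paste0("at_", i)),
      hmm_hit(fams$gpe_id[i], fams$threshold_bits[i] - 0.1, protein = paste0("below_", i))
    )
  }))
  out <- filter_hmm_hits(hits, reg)
  expect_true(all(out$passes_threshold[startsWith(out$protein_id, "at_")]))
  expect_false(any(out$passes_threshold[startsWith(out$protein_id, "below_")]))
})

test_that("the 303-bit uridylyltransferase threshold behaves as published", {
  reg <- load_registry()
  expect_true(filter_hmm_hits(hmm_hit("GPE00530", 303.0), reg)$passes_threshold)
  expect_false(filter_hmm_hits(hmm_hit("GPE00530", 302.9), reg)$passes_threshold)
})

test_that("blast cutoffs are conjunctive and honour per-family overrides", {
  reg <- load_registry()
  # defaults: >=90% coverage and >=30% similarity
  expect_true(filter_blast_hits(blast_hit("GPE90020", 30, 90), reg)$passes_threshold)
  expect_false(filter_blast_hits(blast_hit("GPE90020", 95, 89.9), reg)$passes_threshold)
  expect_false(filter_blast_hits(blast_hit("GPE90020", 29.9, 100), reg)$passes_threshold)
  # the retaining 4,6-dehydratase query was raised to 70% similarity
  expect_false(filter_blast_hits(blast_hit("GPE90010", 65, 95), reg)$passes_threshold)
  expect_true(filter_blast_hits(blast_hit("GPE90010", 70, 95), reg)$passes_threshold)
})

test_that("hits against unregistered or wrong-mode families error", {
  reg <- load_registry()
  expect_error(filter_hmm_hits(hmm_hit("GPE12345", 500), reg), class = "glyco_input_error")
  expect_error(filter_hmm_hits(hmm_hit("GPE90010", 500), reg), class = "glyco_input_error")
  expect_error(filter_blast_hits(blast_hit("GPE00510", 90, 95), reg), class = "glyco_input_error")
})

test_that("filtering is idempotent, order-independent and monotone in the threshold", {
  reg <- tiny_registry()
  set.seed(5)
  hits <- dplyr::bind_rows(lapply(1:40, function(i) {
    hmm_hit(sample(reg$enzyme_families$gpe_id, 1), stats::runif(1, 50, 200), protein = paste0("WP_", i))
  }))
  f1 <- filter_hmm_hits(hits, reg)
  f2 <- filter_hmm_hits(f1, reg)
  expect_equal(f1$passes_threshold, f2$passes_threshold)
  perm <- sample(nrow(hits))
  fp <- filter_hmm_hits(hits[perm, ], reg)
  expect_equal(fp$passes_threshold, f1$passes_threshold[perm])
  # lowering any threshold never shrinks the passing set
  for (delta in c(5, 20, 60)) {
    reg_lo <- reg
    reg_lo$enzyme_families$threshold_bits <- reg$enzyme_families$threshold_bits - delta
    lo <- filter_hmm_hits(hits, reg_lo)
    expect_true(all(lo$passes_threshold >= f1$passes_threshold))
  }
})

test_that("feature tables keep CDS only, ordered by start per replicon", {
  hdr <- paste(c(
    "# feature", "class", "assembly", "assembly_unit", "seq_type", "chromosome",
    "genomic_accession", "start", "end", "strand", "product_accession",
    "non-redundant_refseq", "related_accession", "name", "symbol", "GeneID",
    "locus_tag", "feature_interval_length", "product_length", "attributes"
  ), collapse = "\t")
  row <- function(feature, acc, start, prot) {
    paste(feature, "c", "a", "u", "chromosome", "", acc, start, start + 500, "+",
      prot, "", "", "n", "s", "1", "loc", "500", "166", "",
      sep = "\t"
    )
  }
  lines <- c(
    hdr,
    row("CDS", "NC_1", 5000, "P3"),
    row("gene", "NC_1", 5000, ""),
    row("CDS", "NC_1", 1000, "P1"),
    row("rRNA", "NC_1", 1500, ""),
    row("CDS", "NC_1", 3000, "P2"),
    row("CDS", "NC_2", 9000, "Q2"),
    row("CDS", "NC_2", 100, "Q1")
  )
  path <- write_lines_tmp(lines, "_feature_table.txt")
  feats <- read_feature_table(path, genome_id = "G1")
  # non-CDS rows excluded: 5 CDS of the 7 feature rows (count checked by hand)
  expect_equal(nrow(feats), 5)
  nc1 <- feats[feats$replicon_id == "NC_1", ]
  expect_equal(nc1$protein_id[order(nc1$ordinal_index)], c("P1", "P2", "P3"))
  nc2 <- feats[feats$replicon_id == "NC_2", ]
  expect_equal(nc2$ordinal_index[match(c("Q1", "Q2"), nc2$protein_id)], c(1L, 2L))
})

test_that("feature tables with a foreign header are rejected", {
  path <- write_lines_tmp(c("col1\tcol2", "a\tb"), ".txt")
  err <- expect_error(read_feature_table(path), class = "glyco_input_error")
  expect_match(conditionMessage(err), "product_accession")
})
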