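passing <- function(...) {
  hits <- dplyr::bind_rows(...)
  hits$passes_threshold <- TRUE
  hits
}

test_that("a single passing profile resolves to itself", {
  reg <- load_registry()
  hits <- filter_hmm_hits(hmm_hit("GPE05331", 400), reg)
  out <- resolve_multi_profile(hits, reg)
  expect_equal(out$resolved_gpe_id, "GPE05331")
  expect_equal(out$resolution_reason, "single_pass")
})

test_that("narrow profiles beat their broad seed-superset siblings", {
  reg <- load_registry()
  # the 3,5-epimerase pair: narrow GPE02430 within broad GPE02530, with the
  # broad profile carrying the larger margin -- narrow must still win
  hits <- filter_hmm_hits(dplyr::bind_rows(
    hmm_hit("GPE02430", 155), # margin 5
    hmm_hit("GPE02530", 400) # margin 255
  ), reg)
  out <- resolve_multi_profile(hits, reg)
  expect_equal(out$resolved_gpe_id, "GPE02430")
  expect_equal(out$resolution_reason, "narrow_over_broad")
  # same for the C4-aminotransferase pair
  hits2 <- filter_hmm_hits(dplyr::bind_rows(
    hmm_hit("GPE30310", 180),
    hmm_hit("GPE30010", 300)
  ), reg)
  expect_equal(resolve_multi_profile(hits2, reg)$resolved_gpe_id, "GPE30310")
})

test_that("unrelated multi-passing proteins resolve by largest margin", {
  reg <- load_registry()
  # margins 12.0 (GPE01210: thr 120) and 3.5 (GPE06930: thr 215)
  h1 <- hmm_hit("GPE01210", 132.0)
  h2 <- hmm_hit("GPE06930", 218.5)
  for (ord in list(c(1, 2), c(2, 1))) { # both input orderings agree
    hits <- filter_hmm_hits(dplyr::bind_rows(list(h1, h2)[ord]), reg)
    out <- resolve_multi_profile(hits, reg)
    expect_equal(out$resolved_gpe_id, "GPE01210")
    expect_equal(out$resolution_reason, "margin")
    expect_equal(out$margin, 12.0)
  }
})

test_that("margin ties break to the lexicographically smallest profile", {
  reg <- load_registry()
  hits <- filter_hmm_hits(dplyr::bind_rows(
    hmm_hit("GPE06930", 225), # margin 10
    hmm_hit("GPE01210", 130) # margin 10
  ), reg)
  expect_equal(resolve_multi_profile(hits, reg)$resolved_gpe_id, "GPE01210")
})

test_that("resolution is deterministic and permutation-invariant", {
  reg <- load_registry()
  fams <- reg$enzyme_families[reg$enzyme_families$detection_mode == "hmm_profile", ]
  set.seed(31)
  hits <- dplyr::bind_rows(lapply(1:25, function(i) {
    n <- sample(1:3, 1)
    ix <- sample(nrow(fams), n)
    dplyr::bind_rows(lapply(ix, function(k) {
      hmm_hit(fams$gpe_id[k], fams$threshold_bits[k] + stats::runif(1, 0, 50),
        protein = sprintf("WP_%03d", i)
      )
    }))
  }))
  hits <- filter_hmm_hits(hits, reg)
  base <- resolve_multi_profile(hits, reg)
  for (rep in 1:3) {
    perm <- sample(nrow(hits))
    out <- resolve_multi_profile(hits[perm, ], reg)
    out <- out[match(base$protein_id, out$protein_id), ]
    expect_equal(out$resolved_gpe_id, base$resolved_gpe_id)
    expect_equal(out$resolution_reason, base$resolution_reason)
  }
})

test_that("removing a losing unrelated profile never changes the winner", {
  reg <- load_registry()
  fams <- reg$enzyme_families[
    reg$enzyme_families$detection_mode == "hmm_profile" &
      lengths(reg$enzyme_families$superset_of) == 0 &
      !reg$enzyme_families$gpe_id %in% c("GPE02430", "GPE30310"),
  ]
  set.seed(77)
  for (case in 1:20) {
    ix <- sample(nrow(fams), 3)
    rows <- lapply(ix, function(k) {
      hmm_hit(fams$gpe_id[k], fams$threshold_bits[k] + stats::runif(1, 0, 40))
    })
    full <- filter_hmm_hits(dplyr::bind_rows(rows), reg)
    winner <- resolve_multi_profile(full, reg)$resolved_gpe_id
    losers <- setdiff(full$gpe_id, winner)
    for (drop in losers) {
      red <- full[full$gpe_id != drop, ]
      expect_equal(resolve_multi_profile(red, reg)$resolved_gpe_id, winner)
    }
  }
})

test_that("removing the dominated broad profile keeps the narrow winner", {
  reg <- load_registry()
  full <- filter_hmm_hits(dplyr::bind_rows(
    hmm_hit("GPE02430", 160),
    hmm_hit("GPE02530", 300)
  ), reg)
  narrow_only <- full[full$gpe_id == "GPE02430", ]
  expect_equal(
    resolve_multi_profile(full, reg)$resolved_gpe_id,
    resolve_multi_profile(narrow_only, reg)$resolved_gpe_id
  )
})

# ---- context rules -------------------------------------------------------

context_genome <- function(reg, monos, epimerase_cluster, window_gap = 1) {
  # builds hits + features: one cluster per pathway; the 2-epimerase hit sits
  # inside the cluster named by `epimerase_cluster`
  hmm <- list()
  feats <- list()
  ordn <- 0L
  for (m in monos) {
    sugar <- reg$nucleotide_sugars$sugar_id[reg$nucleotide_sugars$mono_id == m][1]
    rid <- reg$routes$route_id[reg$routes$sugar_id == sugar][1]
    steps <- reg$routes$steps[[which(reg$routes$route_id == rid)]]
    ordn <- ordn + 15L # separate clusters beyond the +/-10 window
    for (j in seq_along(steps)) {
      fam <- steps[[j]][1]
      k <- which(reg$enzyme_families$gpe_id == fam)
      if (reg$enzyme_families$detection_mode[k] != "hmm_profile") next
      ordn <- ordn + window_gap
      prot <- sprintf("WP_%s_%d", m, j)
      hmm[[length(hmm) + 1]] <- hmm_hit(fam, reg$enzyme_families$threshold_bits[k] + 20, protein = prot)
      feats[[length(feats) + 1]] <- tibble::tibble(
        genome_id = "G1", protein_id = prot, replicon_id = "NC_1",
        ordinal_index = ordn, strand = "+"
      )
    }
  }
  list(hmm = dplyr::bind_rows(hmm), features = dplyr::bind_rows(feats))
}

test_that("the 2-epimerase defaults to the Man2NAc pathway without override context", {
  reg <- load_registry()
  g <- context_genome(reg, "man2nac", "man2nac")
  hits <- filter_hmm_hits(g$hmm, reg)
  att <- apply_context_rules(resolve_multi_profile(hits, reg), g$features, reg)
  ep <- att[att$resolved_gpe_id == "GPE02030", ]
  expect_equal(nrow(ep), 1)
  expect_true("man2nac" %in% ep$allowed_monos[[1]])
  expect_false(any(c("l-fuc2nac", "l-qui2nac", "man2nac3naca") %in% ep$allowed_monos[[1]]))
  expect_match(ep$context_reason, "^default:man2nac")
  ga <- propagate_pairs(call_routes(att, reg, "G1"), reg, "G1")
  expect_true("man2nac" %in% ga$present)
})

test_that("an override enzyme within the window redirects the 2-epimerase", {
  reg <- load_registry()
  g <- context_genome(reg, "l-qui2nac", "l-qui2nac")
  hits <- filter_hmm_hits(g$hmm, reg)
  att <- apply_context_rules(resolve_multi_profile(hits, reg), g$features, reg)
  ep <- att[att$resolved_gpe_id == "GPE02030", ]
  expect_true("l-qui2nac" %in% ep$allowed_monos[[1]])
  expect_false("man2nac" %in% ep$allowed_monos[[1]])
  ga <- propagate_pairs(call_routes(att, reg, "G1"), reg, "G1")
  expect_true("l-qui2nac" %in% ga$present)
  expect_false("man2nac" %in% ga$present)
  # the pathway intermediate rides along with the override attribution
  expect_true("l-rha2nac" %in% ga$present)
})

test_that("override enzymes beyond the window do not fire the rule", {
  reg <- load_registry()
  g <- context_genome(reg, "l-qui2nac", "l-qui2nac", window_gap = 30)
  hits <- filter_hmm_hits(g$hmm, reg)
  att <- apply_context_rules(resolve_multi_profile(hits, reg), g$features, reg)
  ep <- att[att$resolved_gpe_id == "GPE02030", ]
  expect_match(ep$context_reason, "^default:")
})

test_that("without a feature table the rule degrades to whole-genome context", {
  reg <- load_registry()
  g <- context_genome(reg, "l-qui2nac", "l-qui2nac", window_gap = 30)
  hits <- filter_hmm_hits(g$hmm, reg)
  att <- apply_context_rules(resolve_multi_profile(hits, reg), NULL, reg)
  ep <- att[att$resolved_gpe_id == "GPE02030", ]
  expect_match(ep$context_reason, "whole-genome context")
  expect_true("l-qui2nac" %in% ep$allowed_monos[[1]])
})

test_that("hits attributed to two override pathways count for both", {
  reg <- load_registry()
  # both Man2NAc3NAcA and l-Qui2NAc enzymes near a single 2-epimerase gene:
  # completeness must come out as the manual calculation for both pathways
  g1 <- context_genome(reg, c("man2nac3naca", "l-qui2nac"), "man2nac3naca", window_gap = 0)
  hits <- filter_hmm_hits(g1$hmm, reg)
  att <- apply_context_rules(resolve_multi_profile(hits, reg), NULL, reg) # whole-genome context
  eps <- att[att$resolved_gpe_id == "GPE02030", ]
  for (i in seq_len(nrow(eps))) {
    expect_true(all(c("man2nac3naca", "l-qui2nac") %in% eps$allowed_monos[[i]]))
  }
  ga <- propagate_pairs(call_routes(att, reg, "G1"), reg, "G1")
  fam_of <- as.list(att$resolved_gpe_id)
  expect_setequal_chr(ga$present, oracle_alphabet(fam_of, reg))
  expect_true(all(c("man2nac3naca", "l-qui2nac") %in% ga$present))
})

test_that("the resolution audit TSV lists candidates, winner and reason", {
  reg <- load_registry()
  hits <- filter_hmm_hits(dplyr::bind_rows(
    hmm_hit("GPE02430", 155),
    hmm_hit("GPE02530", 400)
  ), reg)
  att <- apply_context_rules(resolve_multi_profile(hits, reg), NULL, reg)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_resolution_audit(att, path)
  back <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  expect_equal(back$resolved_gpe_id, "GPE02430")
  expect_match(back$candidates, "GPE02430,GPE02530")
  expect_equal(back$resolution_reason, "narrow_over_broad")
})
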