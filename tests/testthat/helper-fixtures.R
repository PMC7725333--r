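# Fixtures built in code: a tiny registry, raw registry trees for
# validation tests, writers for hit-table snippets, and independent oracle
# evaluators used to cross-check the pipeline.

# ---- tiny registry -------------------------------------------------------

tiny_registry_raw <- function() {
  fam <- function(gpe, thr) {
    list(
      gpe = gpe, annotation = paste0("enzyme ", gpe), mode = "hmm_profile",
      threshold_bits = thr, method = "roc", specificity = "narrow", seeds = 4L
    )
  }
  list(
    monosaccharides = list(
      list(id = "m1", name = "sugar one", short = "M1", enantiomer = "d", ring = "pyranose", backbone = "hexose"),
      list(id = "m2", name = "sugar two", short = "M2", enantiomer = "d", ring = "pyranose", backbone = "hexose"),
      list(id = "m3", name = "sugar three", short = "M3", enantiomer = "l", ring = "pyranose", backbone = "hexose"),
      list(id = "m4", name = "sugar four", short = "M4", enantiomer = "d", ring = "furanose", backbone = "pentose")
    ),
    nucleotide_sugars = list(
      list(id = "udp-m1", mono = "m1", nucleotide = "UDP", routes = list(
        list(id = "udp-m1.1", precursor = "Glc-1-P", steps = list(list("GPE00010")))
      )),
      list(id = "udp-m2", mono = "m2", nucleotide = "UDP", routes = list(
        list(id = "udp-m2.1", precursor = "Glc-1-P", steps = list(list("GPE00010"), list("GPE00020", "GPE00030")))
      )),
      list(id = "udp-m3", mono = "m3", nucleotide = "UDP", routes = list(
        list(id = "udp-m3.1", precursor = "Glc-1-P", steps = list(list("GPE00010"), list("GPE00020", "GPE00030"), list("GPE00040")))
      )),
      list(id = "udp-m4", mono = "m4", nucleotide = "UDP", routes = list(
        list(id = "udp-m4.1", precursor = "Glc-1-P", steps = list(list("GPE00050")))
      ))
    ),
    enzyme_families = list(
      fam("GPE00010", 100), fam("GPE00020", 120), fam("GPE00030", 90),
      fam("GPE00040", 150), fam("GPE00050", 80)
    ),
    precursor_pairs = list(list("m2", "m3")),
    product_pairs = list(),
    context_rules = list()
  )
}

tiny_registry <- function(raw = tiny_registry_raw()) {
  path <- withr::local_tempfile(fileext = ".yaml", .local_envir = parent.frame())
  yaml::write_yaml(raw, path)
  load_registry(path)
}

# hit tibble in the shape filter_hmm_hits() expects
hmm_hit <- function(gpe, bits, protein = "WP_000000001.1", genome = "G1") {
  tibble::tibble(
    genome_id = genome, protein_id = protein, gpe_id = gpe,
    full_bits = bits + 1, best1dom_bits = bits, evalue = 1e-30
  )
}

blast_hit <- function(gpe, sim, cov, protein = "WP_000000001.1", genome = "G1") {
  tibble::tibble(
    genome_id = genome, protein_id = protein, gpe_id = gpe,
    similarity_pct = sim, coverage_pct = cov, evalue = 1e-30
  )
}

# hits that complete a route: one passing protein per step (first family),
# optionally skipping one step
route_hits <- function(reg, route_id, genome = "G1", skip_step = 0, pick = 1) {
  i <- which(reg$routes$route_id == route_id)
  steps <- reg$routes$steps[[i]]
  fams <- reg$enzyme_families
  rows <- list()
  for (j in seq_along(steps)) {
    if (j == skip_step) next
    fam_ids <- steps[[j]]
    fam_id <- fam_ids[min(pick, length(fam_ids))]
    k <- which(fams$gpe_id == fam_id)
    protein <- sprintf("WP_%s_%02d", gsub("[^0-9A-Za-z]", "", route_id), j)
    if (fams$detection_mode[k] == "hmm_profile") {
      rows[[length(rows) + 1]] <- list(hmm = hmm_hit(fam_id, fams$threshold_bits[k] + 10, protein, genome))
    } else {
      rows[[length(rows) + 1]] <- list(blast = blast_hit(
        fam_id, fams$blast_min_similarity[k] + 10,
        fams$blast_min_coverage[k] + 5, protein, genome
      ))
    }
  }
  list(
    hmm = dplyr::bind_rows(lapply(rows, `[[`, "hmm")),
    blast = dplyr::bind_rows(lapply(rows, `[[`, "blast"))
  )
}

# ---- independent oracles -------------------------------------------------

# pair/precursor closure written independently of propagate_pairs()
oracle_closure <- function(detected, reg) {
  present <- detected
  changed <- TRUE
  while (changed) {
    changed <- FALSE
    for (i in seq_len(nrow(reg$product_pairs))) {
      ab <- c(reg$product_pairs$mono_a[i], reg$product_pairs$mono_b[i])
      if (any(ab %in% present) && !all(ab %in% present)) {
        present <- union(present, ab)
        changed <- TRUE
      }
    }
    pp <- reg$precursor_pairs
    add <- setdiff(pp$precursor[pp$product %in% present], present)
    if (length(add)) {
      present <- union(present, add)
      changed <- TRUE
    }
  }
  sort(present)
}

# brute-force alphabet: enumerate every route x step x hit combination over
# plain family sets (whole-genome context for rule families)
oracle_alphabet <- function(fam_of_protein, reg) {
  fams_present <- unname(unlist(fam_of_protein))
  rules <- reg$context_rules
  detected <- character()
  for (i in seq_len(nrow(reg$routes))) {
    mono <- reg$nucleotide_sugars$mono_id[reg$nucleotide_sugars$sugar_id == reg$routes$sugar_id[i]]
    ok <- TRUE
    for (step in reg$routes$steps[[i]]) {
      sat <- FALSE
      for (f in fams_present) {
        if (!f %in% step) next
        r <- which(rules$gpe_id == f)
        if (length(r) == 0) {
          sat <- TRUE
          break
        }
        overrides <- rules$overrides[[r]]
        others <- setdiff(fams_present, f)
        found <- overrides[vapply(
          overrides,
          function(m) length(intersect(setdiff(glycoscan:::mono_family_set(reg, m), f), others)) > 0,
          logical(1)
        )]
        containing <- reg$monosaccharides$mono_id[vapply(
          reg$monosaccharides$mono_id,
          function(m) f %in% glycoscan:::mono_family_set(reg, m), logical(1)
        )]
        allowed <- if (length(found)) {
          # overrides found, plus their sub-route pathways: those whose
          # families all lie inside an override's and overlap it beyond f
          extra <- Filter(function(m) {
            fs <- glycoscan:::mono_family_set(reg, m)
            any(vapply(found, function(o) {
              os <- glycoscan:::mono_family_set(reg, o)
              all(fs %in% os) && length(intersect(fs, setdiff(os, f))) > 0
            }, logical(1)))
          }, setdiff(containing, found))
          c(found, extra)
        } else {
          setdiff(containing, overrides)
        }
        if (mono %in% allowed) {
          sat <- TRUE
          break
        }
      }
      if (!sat) {
        ok <- FALSE
        break
      }
    }
    if (ok) detected <- union(detected, mono)
  }
  oracle_closure(sort(detected), reg)
}

# confusion matrix at one inclusive threshold, by direct counting
oracle_confusion <- function(scores, labels, t) {
  pred <- scores >= t
  c(
    tp = sum(pred & labels), fp = sum(pred & !labels),
    fn = sum(!pred & labels), tn = sum(!pred & !labels)
  )
}

expect_setequal_chr <- function(a, b) {
  expect_true(setequal(a, b), label = paste0(
    "setequal({", paste(sort(a), collapse = ","), "}, {",
    paste(sort(b), collapse = ","), "})"
  ))
}
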