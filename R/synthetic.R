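#' Specify a synthetic genome universe
#'
#' The generator plants pathway gene clusters in synthetic genomes and
#' emits exactly the artefacts the pipeline consumes (HMMER tblout, BLAST
#' tabular, NCBI-style feature tables, a taxonomy table) together with the
#' planted ground truth, so the whole inference chain can be validated
#' closed-loop with no downloads.
#'
#' @param n_phyla Number of phyla (the first is labelled Archaea).
#' @param n_species_per_phylum Species per phylum.
#' @param n_strains_range Range (min, max) of sequenced strains per species.
#' @param alphabet_sizes Either a length-2 range from which per-species
#'   target alphabet sizes are drawn uniformly, or an explicit integer
#'   vector of targets recycled across species in order.
#' @param decoy_rate Expected number of sub-threshold decoy hits per genome
#'   (Poisson); decoys always score strictly below the family cutoff.
#' @param ambiguity_rate Fraction of planted hits against narrow-specificity
#'   profiles that additionally pass their broad superset sibling.
#' @param dropout_rate Fraction of planted pathway clusters with one step
#'   deleted, creating partial pathways.
#' @param strain_jitter For species with several strains, probability that a
#'   non-reference strain loses one planted pathway cluster (creates
#'   strain-level alphabet-size ranges).
#' @param score_offset Minimum bits (or percent) by which planted hits clear
#'   their threshold; keeps float formatting away from the boundary.
#' @param score_sd Spread of planted scores above `threshold + score_offset`.
#' @param seed Random seed; a fixed seed makes the universe byte-identical
#'   across runs.
#' @return A `glyco_universe_spec`.
#' @export
universe_spec <- function(n_phyla = 5, n_species_per_phylum = 8,
                          n_strains_range = c(1, 5),
                          alphabet_sizes = c(0, 23),
                          decoy_rate = 3, ambiguity_rate = 0, dropout_rate = 0,
                          strain_jitter = 0.5,
                          score_offset = 5, score_sd = 10, seed = 1) {
  spec <- structure(
    list(
      n_phyla = as.integer(n_phyla),
      n_species_per_phylum = as.integer(n_species_per_phylum),
      n_strains_range = as.integer(n_strains_range),
      alphabet_sizes = as.integer(alphabet_sizes),
      decoy_rate = decoy_rate, ambiguity_rate = ambiguity_rate,
      dropout_rate = dropout_rate, strain_jitter = strain_jitter,
      score_offset = score_offset, score_sd = score_sd,
      seed = as.integer(seed),
      planting_probs = NULL
    ),
    class = "glyco_universe_spec"
  )
  validate_universe_spec(spec)
  spec
}

validate_universe_spec <- function(spec) {
  v <- character()
  if (spec$n_phyla < 1) v <- c(v, "n_phyla must be >= 1")
  if (spec$n_species_per_phylum < 1) v <- c(v, "n_species_per_phylum must be >= 1")
  if (length(spec$n_strains_range) != 2 || spec$n_strains_range[1] < 1 ||
    spec$n_strains_range[2] < spec$n_strains_range[1]) {
    v <- c(v, "n_strains_range must be (min, max) with 1 <= min <= max")
  }
  if (any(spec$alphabet_sizes < 0)) v <- c(v, "alphabet_sizes must be non-negative")
  for (f in c("decoy_rate", "ambiguity_rate", "dropout_rate", "strain_jitter")) {
    if (spec[[f]] < 0) v <- c(v, paste0(f, " must be >= 0"))
  }
  for (f in c("ambiguity_rate", "dropout_rate", "strain_jitter")) {
    if (spec[[f]] > 1) v <- c(v, paste0(f, " must be <= 1"))
  }
  if (spec$score_offset <= 0) v <- c(v, "score_offset must be > 0")
  if (spec$score_sd < 0) v <- c(v, "score_sd must be >= 0")
  if (length(v)) validation_error(v)
  invisible(spec)
}

#' Set per-monosaccharide planting probabilities
#'
#' Switches the generator from alphabet-size targeting to prevalence
#' targeting: each genome plants the canonical pathway of monosaccharide
#' `m` independently with probability `target_fractions[m]` (default 0 for
#' unlisted monosaccharides), so the expected prevalence of a planted
#' monosaccharide equals its target. Targets must respect precursor
#' closure: a product may not be targeted above its precursor, since
#' calling the product always implies the precursor.
#'
#' @param spec A `glyco_universe_spec`.
#' @param reg A `glyco_registry`.
#' @param target_fractions Named numeric vector of fractions in \[0, 1\],
#'   names are monosaccharide ids.
#' @return The spec with `planting_probs` set.
#' @export
plant_prevalence_profile <- function(spec, reg, target_fractions) {
  if (any(target_fractions < 0 | target_fractions > 1)) {
    input_error("target fractions must lie in [0, 1]")
  }
  unknown <- setdiff(names(target_fractions), reg$monosaccharides$mono_id)
  if (length(unknown)) input_error(paste0("unknown monosaccharides in targets: ", paste(unknown, collapse = ", ")))
  probs <- stats::setNames(rep(0, nrow(reg$monosaccharides)), reg$monosaccharides$mono_id)
  probs[names(target_fractions)] <- target_fractions
  pp <- reg$precursor_pairs
  bad <- pp$product[probs[pp$product] > probs[pp$precursor]]
  if (length(bad)) {
    validation_error(paste0(
      "target for product '", bad,
      "' exceeds its precursor's target; precursor closure would raise the precursor's prevalence above target"
    ))
  }
  spec$planting_probs <- probs
  spec
}

# ---- constructive ground truth ------------------------------------------

# clusters: list of list(sugar_id, mono_id, route_id, fams (chr, one per
# step), proteins (chr), ordinals (int)); the truth is derived from the
# emitted gene content by set logic, independent of the parsing/threshold
# machinery it validates.
truth_alphabet <- function(clusters, reg) {
  if (length(clusters) == 0) {
    hit_fams <- character()
    hit_ord <- integer()
  } else {
    hit_fams <- unlist(lapply(clusters, `[[`, "fams"), use.names = FALSE)
    hit_ord <- unlist(lapply(clusters, `[[`, "ordinals"), use.names = FALSE)
  }

  # context emulation for substrate-ambiguous families; non-ruled families
  # are unrestricted
  rules <- reg$context_rules
  is_ruled <- hit_fams %in% rules$gpe_id
  free_fams <- unique(hit_fams[!is_ruled])
  restricted <- list() # per ruled hit: list(fam, allowed)
  for (k in which(is_ruled)) {
    fam <- hit_fams[k]
    r <- which(rules$gpe_id == fam)
    overrides <- rules$overrides[[r]]
    window <- rules$window[r]
    near <- hit_fams[abs(hit_ord - hit_ord[k]) <= window & hit_ord != hit_ord[k]]
    found <- overrides[vapply(overrides, function(m) {
      length(intersect(setdiff(mono_family_set(reg, m), fam), near)) > 0
    }, logical(1))]
    containing <- reg$monosaccharides$mono_id[vapply(
      reg$monosaccharides$mono_id,
      function(m) fam %in% mono_family_set(reg, m), logical(1)
    )]
    allowed <- if (length(found)) {
      fam_sets <- lapply(containing, function(m) mono_family_set(reg, m))
      names(fam_sets) <- containing
      context_override_allowed(found, containing, fam_sets, fam)
    } else {
      setdiff(containing, overrides)
    }
    restricted[[length(restricted) + 1]] <- list(fam = fam, allowed = allowed)
  }

  mono_of <- stats::setNames(reg$nucleotide_sugars$mono_id, reg$nucleotide_sugars$sugar_id)
  detected <- character()
  for (i in seq_len(nrow(reg$routes))) {
    mono <- mono_of[[reg$routes$sugar_id[i]]]
    ok <- all(vapply(reg$routes$steps[[i]], function(step) {
      if (any(step %in% free_fams)) {
        return(TRUE)
      }
      any(vapply(restricted, function(rh) rh$fam %in% step && mono %in% rh$allowed, logical(1)))
    }, logical(1)))
    if (ok) detected <- union(detected, mono)
  }

  present <- detected
  repeat {
    new <- present
    for (i in seq_len(nrow(reg$product_pairs))) {
      ab <- c(reg$product_pairs$mono_a[i], reg$product_pairs$mono_b[i])
      if (any(ab %in% new)) new <- union(new, ab)
    }
    pp <- reg$precursor_pairs
    new <- union(new, pp$precursor[pp$product %in% new])
    if (setequal(new, present)) break
    present <- new
  }
  list(present = sort_ids(present), detected = sort_ids(detected))
}

# ---- universe generation -------------------------------------------------

#' Generate a synthetic universe with planted ground truth
#'
#' Every genome receives contiguous gene clusters for its planted pathway
#' routes (emulating O-antigen-cluster-style layouts), with hit scores
#' clearing family thresholds by at least `score_offset`; decoy hits score
#' strictly below threshold; optional ambiguous hits also pass a sibling
#' profile; optional dropout deletes one step per affected cluster. The
#' ground truth is derived constructively from the emitted gene content
#' (route-coverage closure, context emulation, product-pair and precursor
#' closure), so it is exactly what a correct pipeline must recover.
#'
#' @param spec A `glyco_universe_spec`.
#' @param reg A `glyco_registry`.
#' @param dir Optional directory; when given, the universe is also written
#'   to disk via [write_universe()].
#' @return A `glyco_universe`: list with `taxonomy`, `hmm_hits`,
#'   `blast_hits`, `features`, `truth` (per-genome list), `spec`.
#' @export
generate_universe <- function(spec, reg, dir = NULL) {
  validate_universe_spec(spec)
  if (is.null(spec$planting_probs) && length(spec$alphabet_sizes) == 2) {
    max_monos <- nrow(reg$monosaccharides)
    if (max(spec$alphabet_sizes) > max_monos) {
      validation_error(paste0(
        "alphabet size target ", max(spec$alphabet_sizes),
        " exceeds the ", max_monos, " monosaccharides in the registry"
      ))
    }
  }
  set.seed(spec$seed)

  fams <- reg$enzyme_families
  thr_of <- stats::setNames(fams$threshold_bits, fams$gpe_id)
  sim_of <- stats::setNames(fams$blast_min_similarity, fams$gpe_id)
  cov_of <- stats::setNames(fams$blast_min_coverage, fams$gpe_id)
  mode_of <- stats::setNames(fams$detection_mode, fams$gpe_id)
  # narrow profile -> the broad sibling generated from a seed superset
  narrow_to_broad <- list()
  for (i in seq_len(nrow(fams))) {
    for (n in fams$superset_of[[i]]) narrow_to_broad[[n]] <- fams$gpe_id[i]
  }
  mono_of <- stats::setNames(reg$nucleotide_sugars$mono_id, reg$nucleotide_sugars$sugar_id)

  # --- taxonomy skeleton ---
  tax_rows <- list()
  gcount <- 0L
  species_list <- list()
  for (p in seq_len(spec$n_phyla)) {
    phylum <- sprintf("Phylum_%02d", p)
    domain <- if (p == 1) "Archaea" else "Bacteria"
    for (s in seq_len(spec$n_species_per_phylum)) {
      species <- sprintf("Species_%02d_%02d", p, s)
      genus <- sprintf("Genus_%02d_%02d", p, ceiling(s / 2))
      strain_choices <- spec$n_strains_range[1]:spec$n_strains_range[2]
      n_strains <- strain_choices[sample.int(length(strain_choices), 1)]
      genomes <- character(n_strains)
      for (k in seq_len(n_strains)) {
        gcount <- gcount + 1L
        genomes[k] <- sprintf("GCF_%06d.1", gcount)
      }
      species_list[[length(species_list) + 1]] <- list(
        species = species, genus = genus, phylum = phylum, domain = domain,
        genomes = genomes
      )
    }
  }

  # --- choose planted clusters per species / strain ---
  pick_route <- function(sugar_id) {
    rids <- reg$routes$route_id[reg$routes$sugar_id == sugar_id]
    rid <- if (length(rids) == 1) rids else sample(rids, 1)
    steps <- reg$routes$steps[[which(reg$routes$route_id == rid)]]
    fams_pick <- vapply(steps, function(st) if (length(st) == 1) st else sample(st, 1), "")
    list(sugar_id = sugar_id, mono_id = mono_of[[sugar_id]], route_id = rid, fams = fams_pick)
  }

  plan_species <- function(target) {
    picks <- list()
    truth_size <- 0L
    remaining <- sample(reg$nucleotide_sugars$sugar_id)
    for (sug in remaining) {
      if (truth_size >= target) break
      if (sug %in% vapply(picks, `[[`, "", "sugar_id")) next
      cand <- pick_route(sug)
      # ordinals mimic the emitted layout: contiguous within a cluster,
      # clusters far apart, so the planning-time truth matches emission
      trial <- c(picks, list(c(cand, list(
        proteins = character(),
        ordinals = seq_along(cand$fams) + length(picks) * 10000L
      ))))
      tsize <- length(truth_alphabet(trial, reg)$present)
      if (tsize <= target) {
        picks <- trial
        truth_size <- tsize
      }
    }
    picks
  }

  sizes_cfg <- spec$alphabet_sizes
  n_species <- length(species_list)
  targets <- if (!is.null(spec$planting_probs)) {
    rep(NA_integer_, n_species)
  } else if (length(sizes_cfg) == 2) {
    size_choices <- sizes_cfg[1]:sizes_cfg[2]
    size_choices[sample.int(length(size_choices), n_species, replace = TRUE)]
  } else {
    rep(sizes_cfg, length.out = n_species)
  }

  hmm_rows <- list()
  blast_rows <- list()
  feat_rows <- list()
  tax_out <- list()
  truth <- list()
  pcount <- 0L

  new_protein <- function() {
    pcount <<- pcount + 1L
    sprintf("WP_%09d.1", pcount)
  }

  for (si in seq_along(species_list)) {
    sp <- species_list[[si]]
    base_picks <- if (!is.null(spec$planting_probs)) {
      probs <- spec$planting_probs
      planted <- names(probs)[stats::runif(length(probs)) < probs]
      lapply(canonical_sugars(reg, planted), pick_route)
    } else {
      lapply(plan_species(targets[si]), function(p) p[c("sugar_id", "mono_id", "route_id", "fams")])
    }

    for (k in seq_along(sp$genomes)) {
      gid <- sp$genomes[k]
      picks <- base_picks
      if (!is.null(spec$planting_probs) && k > 1) {
        # independent draw per strain under prevalence targeting
        probs <- spec$planting_probs
        planted <- names(probs)[stats::runif(length(probs)) < probs]
        picks <- lapply(canonical_sugars(reg, planted), pick_route)
      } else if (k > 1 && length(picks) > 0 && stats::runif(1) < spec$strain_jitter) {
        picks <- picks[-sample(length(picks), 1)]
      }

      g <- emit_genome(
        gid, picks, reg, spec,
        thr_of, sim_of, cov_of, mode_of, narrow_to_broad, new_protein
      )
      hmm_rows[[length(hmm_rows) + 1]] <- g$hmm
      blast_rows[[length(blast_rows) + 1]] <- g$blast
      feat_rows[[length(feat_rows) + 1]] <- g$features
      tt <- truth_alphabet(g$clusters, reg)
      truth[[gid]] <- list(
        monosaccharides = tt$present,
        detected = tt$detected,
        implied = setdiff(tt$present, tt$detected),
        planted_sugars = sort_ids(vapply(g$clusters, `[[`, "", "sugar_id")),
        dropped_sugars = g$dropped,
        ambiguous_proteins = g$ambiguous
      )
      # the emitted feature rows cover the pathway loci and their
      # neighbourhoods; the proteome at large is an independent baseline,
      # so alphabet size stays independent of proteome size as in real
      # prokaryotes
      tax_out[[length(tax_out) + 1]] <- tibble(
        genome_id = gid, species = sp$species, genus = sp$genus,
        phylum = sp$phylum, domain = sp$domain,
        proteome_size = nrow(g$features) + sample(1500:6000, 1)
      )
    }
  }

  uni <- structure(
    list(
      taxonomy = dplyr::bind_rows(tax_out),
      hmm_hits = dplyr::bind_rows(hmm_rows),
      blast_hits = dplyr::bind_rows(blast_rows),
      features = dplyr::bind_rows(feat_rows),
      truth = truth,
      spec = spec
    ),
    class = "glyco_universe"
  )
  if (!is.null(dir)) write_universe(uni, dir)
  uni
}

# one canonical nucleotide sugar per monosaccharide (first in registry order)
canonical_sugars <- function(reg, monos) {
  sug <- reg$nucleotide_sugars
  vapply(monos[monos %in% sug$mono_id], function(m) sug$sugar_id[sug$mono_id == m][1], "")
}

emit_genome <- function(gid, picks, reg, spec, thr_of, sim_of, cov_of, mode_of,
                        narrow_to_broad, new_protein) {
  replicon <- sub("^GCF", "NC", sub("\\.1$", "", gid))
  window_pad <- max(c(reg$context_rules$window, 10L)) + 2L

  genes <- list() # protein_id, family (NA for filler), cluster index
  add_gene <- function(protein, family, cluster) {
    genes[[length(genes) + 1]] <<- list(protein = protein, family = family, cluster = cluster)
  }
  fillers <- function(n) for (i in seq_len(n)) add_gene(new_protein(), NA_character_, 0L)

  dropped <- character()
  clusters <- list()
  fillers(5L)
  for (ci in seq_along(picks)) {
    pk <- picks[[ci]]
    drop_step <- 0L
    if (spec$dropout_rate > 0 && stats::runif(1) < spec$dropout_rate) {
      drop_step <- sample(length(pk$fams), 1)
      dropped <- c(dropped, pk$sugar_id)
    }
    proteins <- character(length(pk$fams))
    ords <- integer(length(pk$fams))
    keep <- rep(TRUE, length(pk$fams))
    for (j in seq_along(pk$fams)) {
      if (j == drop_step) {
        keep[j] <- FALSE
        next
      }
      proteins[j] <- new_protein()
      add_gene(proteins[j], pk$fams[j], ci)
    }
    clusters[[length(clusters) + 1]] <- list(
      sugar_id = pk$sugar_id, mono_id = pk$mono_id, route_id = pk$route_id,
      fams = pk$fams[keep], proteins = proteins[keep], ordinals = integer(0)
    )
    fillers(window_pad)
  }
  # decoys live in a trailing segment, padded away from real clusters
  n_decoys <- stats::rpois(1, spec$decoy_rate)
  decoy_proteins <- character(n_decoys)
  decoy_fams <- character(n_decoys)
  if (n_decoys > 0) {
    all_fams <- names(thr_of)
    for (d in seq_len(n_decoys)) {
      decoy_proteins[d] <- new_protein()
      decoy_fams[d] <- sample(all_fams, 1)
      add_gene(decoy_proteins[d], NA_character_, -1L)
    }
  }
  fillers(5L)

  # ordinals by position; record them back onto clusters for the truth logic
  n <- length(genes)
  protein_ids <- vapply(genes, `[[`, "", "protein")
  cluster_ix <- vapply(genes, `[[`, 0L, "cluster")
  ord_of <- stats::setNames(seq_len(n), protein_ids)
  for (ci in seq_along(clusters)) {
    clusters[[ci]]$ordinals <- unname(ord_of[clusters[[ci]]$proteins])
  }

  # --- hit rows ---
  ambiguous <- character()
  hmm <- list()
  blast <- list()
  rnd <- function(x) round(x, 1)
  add_hmm <- function(protein, fam, bits) {
    hmm[[length(hmm) + 1]] <<- tibble(
      genome_id = gid, protein_id = protein, gpe_id = fam,
      full_bits = rnd(bits + stats::runif(1, 0, 5)),
      best1dom_bits = rnd(bits),
      evalue = 10^(-bits / 10)
    )
  }
  add_blast <- function(protein, fam, sim, cov) {
    blast[[length(blast) + 1]] <<- tibble(
      genome_id = gid, protein_id = protein, gpe_id = fam,
      similarity_pct = rnd(sim), coverage_pct = rnd(cov), evalue = 1e-50
    )
  }

  for (cl in clusters) {
    for (j in seq_along(cl$fams)) {
      fam <- cl$fams[j]
      protein <- cl$proteins[j]
      if (mode_of[[fam]] == "hmm_profile") {
        bits <- thr_of[[fam]] + spec$score_offset + abs(stats::rnorm(1, 0, spec$score_sd))
        add_hmm(protein, fam, bits)
        broad <- narrow_to_broad[[fam]]
        if (!is.null(broad) && spec$ambiguity_rate > 0 && stats::runif(1) < spec$ambiguity_rate) {
          add_hmm(protein, broad, thr_of[[broad]] + 1 + abs(stats::rnorm(1, 0, spec$score_sd / 4)))
          ambiguous <- c(ambiguous, protein)
        }
      } else {
        sim <- min(99.9, sim_of[[fam]] + spec$score_offset + abs(stats::rnorm(1, 0, spec$score_sd / 2)))
        cov <- min(100, cov_of[[fam]] + stats::runif(1, 1, 100 - cov_of[[fam]]))
        add_blast(protein, fam, sim, cov)
      }
    }
  }
  for (d in seq_along(decoy_proteins)) {
    fam <- decoy_fams[d]
    if (mode_of[[fam]] == "hmm_profile") {
      bits <- max(1, thr_of[[fam]] - spec$score_offset - abs(stats::rnorm(1, 0, spec$score_sd)))
      add_hmm(decoy_proteins[d], fam, bits)
    } else {
      sim <- max(1, sim_of[[fam]] - spec$score_offset - abs(stats::rnorm(1, 0, spec$score_sd / 2)))
      add_blast(decoy_proteins[d], fam, sim, stats::runif(1, 50, 100))
    }
  }

  features <- tibble(
    genome_id = gid,
    protein_id = protein_ids,
    replicon_id = replicon,
    ordinal_index = seq_len(n),
    strand = rep_len(c("+", "-"), n)
  )

  empty_hmm <- tibble(
    genome_id = character(), protein_id = character(), gpe_id = character(),
    full_bits = numeric(), best1dom_bits = numeric(), evalue = numeric()
  )
  empty_blast <- tibble(
    genome_id = character(), protein_id = character(), gpe_id = character(),
    similarity_pct = numeric(), coverage_pct = numeric(), evalue = numeric()
  )
  list(
    hmm = if (length(hmm)) dplyr::bind_rows(hmm) else empty_hmm,
    blast = if (length(blast)) dplyr::bind_rows(blast) else empty_blast,
    features = features,
    clusters = clusters,
    dropped = sort_ids(unique(dropped)),
    ambiguous = sort_ids(unique(ambiguous))
  )
}

#' @export
print.glyco_universe <- function(x, ...) {
  cat(
    "<glyco_universe> ", nrow(x$taxonomy), " genomes, ",
    length(unique(x$taxonomy$species)), " species, ",
    length(unique(x$taxonomy$phylum)), " phyla; ",
    nrow(x$hmm_hits), " HMM hit rows, ", nrow(x$blast_hits), " blast hit rows\n",
    sep = ""
  )
  invisible(x)
}

# ---- serialization -------------------------------------------------------

#' Write a universe to disk in the pipeline's input formats
#'
#' Layout: `hits/<genome>.tblout`, `blast/<genome>.blast.tsv` (only for
#' genomes with blast rows), `features/<genome>_feature_table.txt`,
#' `taxonomy.tsv`, `ground_truth.json`. Output is deterministic: the same
#' spec and seed give byte-identical files.
#'
#' @param uni A `glyco_universe`.
#' @param dir Output directory (created if needed).
#' @export
write_universe <- function(uni, dir) {
  for (d in c("", "hits", "blast", "features")) {
    dir.create(file.path(dir, d), recursive = TRUE, showWarnings = FALSE)
  }
  genomes <- uni$taxonomy$genome_id
  for (gid in genomes) {
    write_tblout(uni$hmm_hits[uni$hmm_hits$genome_id == gid, ], file.path(dir, "hits", paste0(gid, ".tblout")))
    b <- uni$blast_hits[uni$blast_hits$genome_id == gid, ]
    if (nrow(b)) write_blast_tsv(b, file.path(dir, "blast", paste0(gid, ".blast.tsv")))
    write_feature_table(
      uni$features[uni$features$genome_id == gid, ],
      file.path(dir, "features", paste0(gid, "_feature_table.txt"))
    )
  }
  utils::write.table(uni$taxonomy, file.path(dir, "taxonomy.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  jsonlite::write_json(uni$truth, file.path(dir, "ground_truth.json"),
    auto_unbox = FALSE, pretty = TRUE, digits = NA
  )
  invisible(dir)
}

write_tblout <- function(hits, path) {
  con <- file(path, open = "wb") # binary: stable newlines across platforms
  on.exit(close(con))
  hdr <- c(
    "#                                                               --- full sequence ---- --- best 1 domain ---- --- domain number estimation ----",
    "# target name        accession  query name           accession    E-value  score  bias   E-value  score  bias   exp reg clu  ov env dom rep inc description of target",
    "#------------------- ---------- -------------------- ---------- --------- ------ ----- --------- ------ ----- ----- --- --- --- --- --- --- --- ---------------------"
  )
  writeLines(hdr, con)
  if (nrow(hits)) {
    lines <- sprintf(
      "%-20s %-10s %-20s %-10s %9.2g %6.1f %5.1f %9.2g %6.1f %5.1f %5.1f %3d %3d %3d %3d %3d %3d %3d %s",
      hits$protein_id, "-", hits$gpe_id, "-",
      hits$evalue, hits$full_bits, 0,
      hits$evalue, hits$best1dom_bits, 0,
      1, 1, 1, 1, 1, 1, 1, 1, "synthetic protein"
    )
    writeLines(lines, con)
  }
  writeLines("#", con)
  invisible(path)
}

write_blast_tsv <- function(hits, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  qlen <- 300L
  len <- as.integer(ceiling(qlen * hits$coverage_pct / 100))
  lines <- sprintf(
    "%s\t%s\t%.1f\t%.1f\t%d\t%d\t%.2g\t%.1f",
    hits$gpe_id, hits$protein_id, hits$similarity_pct, hits$similarity_pct,
    len, qlen, hits$evalue, 2 * hits$similarity_pct
  )
  writeLines(lines, con)
  invisible(path)
}

write_feature_table <- function(features, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  cols <- c(
    "# feature", "class", "assembly", "assembly_unit", "seq_type", "chromosome",
    "genomic_accession", "start", "end", "strand", "product_accession",
    "non-redundant_refseq", "related_accession", "name", "symbol", "GeneID",
    "locus_tag", "feature_interval_length", "product_length", "attributes"
  )
  writeLines(paste(cols, collapse = "\t"), con)
  gid <- features$genome_id[1] %||% "genome"
  start <- 1000L * features$ordinal_index + 1L
  end <- start + 899L
  row <- function(feature, class, start, end, strand, prot, locus) {
    paste(feature, class, gid, "Primary Assembly", "chromosome", "",
      features$replicon_id[1], start, end, strand, prot, "", "", "synthetic protein",
      "", "", locus, 900, 299, "",
      sep = "\t"
    )
  }
  lines <- character(0)
  for (i in seq_len(nrow(features))) {
    locus <- sprintf("SYN_%05d", features$ordinal_index[i])
    lines <- c(
      lines,
      row("gene", "protein_coding", start[i], end[i], features$strand[i], "", locus),
      row("CDS", "with_protein", start[i], end[i], features$strand[i], features$protein_id[i], locus)
    )
  }
  # one structural RNA row exercises non-CDS filtering downstream
  lines <- c(lines, row("rRNA", "rRNA_16S", max(end) + 1000L, max(end) + 2500L, "+", "", "SYN_RRNA1"))
  writeLines(lines, con)
  invisible(path)
}

#' Read a universe directory back into memory
#'
#' Inverse of [write_universe()]: parses the hit tables, feature tables and
#' taxonomy with the same readers the pipeline uses on real data.
#'
#' @param dir Universe directory.
#' @return A list with `taxonomy`, `hmm_hits`, `blast_hits`, `features`,
#'   `truth` (when `ground_truth.json` is present).
#' @export
read_universe <- function(dir) {
  tax_path <- file.path(dir, "taxonomy.tsv")
  if (!file.exists(tax_path)) input_error(paste0("no taxonomy.tsv under ", dir))
  taxonomy <- as_tibble(utils::read.table(tax_path, sep = "\t", header = TRUE, stringsAsFactors = FALSE))
  hmm <- list()
  blast <- list()
  feats <- list()
  for (gid in taxonomy$genome_id) {
    hp <- file.path(dir, "hits", paste0(gid, ".tblout"))
    if (file.exists(hp)) hmm[[gid]] <- read_hmmer_table(hp, "tblout", genome_id = gid)
    bp <- file.path(dir, "blast", paste0(gid, ".blast.tsv"))
    if (file.exists(bp)) blast[[gid]] <- read_blast_table(bp, genome_id = gid)
    fp <- file.path(dir, "features", paste0(gid, "_feature_table.txt"))
    if (file.exists(fp)) feats[[gid]] <- read_feature_table(fp, genome_id = gid)
  }
  truth_path <- file.path(dir, "ground_truth.json")
  truth <- if (file.exists(truth_path)) jsonlite::read_json(truth_path, simplifyVector = TRUE) else NULL
  list(
    taxonomy = taxonomy,
    hmm_hits = dplyr::bind_rows(hmm),
    blast_hits = dplyr::bind_rows(blast),
    features = dplyr::bind_rows(feats),
    truth = truth
  )
}
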