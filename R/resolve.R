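#' Resolve proteins that pass thresholds for more than one profile
#'
#' Each passing protein receives exactly one family annotation:
#'
#' 1. a protein passing a single profile keeps it (`single_pass`);
#' 2. if a narrow-specificity profile passes together with a broad profile
#'    whose seed set is a superset of the narrow profile's seeds (recorded
#'    as `superset_of` in the registry), the broad profile is discarded —
#'    the narrow annotation wins (`narrow_over_broad`);
#' 3. otherwise the profile with the largest margin above its own threshold
#'    wins (`margin`); ties break to the lexicographically smallest family
#'    id, keeping resolution deterministic.
#'
#' For blast-query families the margin is the smaller of the similarity and
#' coverage excesses over their cutoffs, making mixed-mode comparisons
#' deterministic if they ever arise.
#'
#' @param hits Filtered hits (HMM and/or blast rows bound together) with a
#'   `passes_threshold` column; non-passing rows are dropped.
#' @param reg A `glyco_registry`.
#' @return A tibble with one row per passing protein: `genome_id`,
#'   `protein_id`, `resolved_gpe_id`, `resolution_reason`, `margin`,
#'   `candidates` (comma-separated passing profiles, for the audit trail).
#' @export
resolve_multi_profile <- function(hits, reg) {
  if (!"passes_threshold" %in% names(hits)) {
    input_error("hits must be filtered (no passes_threshold column); run filter_hmm_hits()/filter_blast_hits() first")
  }
  hits <- hits[hits$passes_threshold, , drop = FALSE]
  if (nrow(hits) == 0) {
    return(tibble(
      genome_id = character(), protein_id = character(),
      resolved_gpe_id = character(), resolution_reason = character(),
      margin = numeric(), candidates = character()
    ))
  }
  fams <- reg$enzyme_families
  idx <- match(hits$gpe_id, fams$gpe_id)
  margin <- ifelse(
    fams$detection_mode[idx] == "hmm_profile",
    hits$best1dom_bits - fams$threshold_bits[idx],
    pmin(
      hits$similarity_pct - fams$blast_min_similarity[idx],
      hits$coverage_pct - fams$blast_min_coverage[idx]
    )
  )
  hits$margin <- margin

  # broad -> its narrow subsets (profiles generated from seed subsets)
  broad_map <- stats::setNames(fams$superset_of, fams$gpe_id)

  # order rows deterministically, then resolve per protein
  hits <- hits[order(hits$genome_id, hits$protein_id, hits$gpe_id, method = "radix"), ]
  key <- paste(hits$genome_id, hits$protein_id, sep = "\r")
  n_per <- table(factor(key, levels = unique(key)))

  pick <- integer(length(n_per))
  reason <- character(length(n_per))
  cand_str <- character(length(n_per))
  offset <- 0L
  for (g in seq_along(n_per)) {
    ix <- offset + seq_len(n_per[[g]])
    offset <- offset + n_per[[g]]
    cand <- hits$gpe_id[ix]
    cand_str[g] <- paste(cand, collapse = ",")
    if (length(cand) == 1) {
      pick[g] <- ix[1]
      reason[g] <- "single_pass"
      next
    }
    marg <- hits$margin[ix]
    # drop broad profiles dominated by a passing narrow subset profile
    dominated <- vapply(cand, function(gp) length(intersect(broad_map[[gp]], cand)) > 0, logical(1))
    keep <- which(!dominated)
    if (length(keep) == 0) keep <- seq_along(cand)
    if (length(keep) == 1 && any(dominated)) {
      pick[g] <- ix[keep]
      reason[g] <- "narrow_over_broad"
    } else {
      best <- keep[order(-marg[keep], cand[keep], method = "radix")][1]
      pick[g] <- ix[best]
      reason[g] <- if (any(dominated)) "narrow_over_broad" else "margin"
    }
  }
  tibble(
    genome_id = hits$genome_id[pick], protein_id = hits$protein_id[pick],
    resolved_gpe_id = hits$gpe_id[pick], resolution_reason = reason,
    margin = hits$margin[pick], candidates = cand_str
  )
}

#' Attribute substrate-ambiguous hits to pathways by genomic context
#'
#' Families covered by a context rule (for example the non-hydrolysing
#' UDP-Glc2NAc 2-epimerase) sit in the pathways of several monosaccharides.
#' A hit for such a family is attributed to the rule's default pathway (and
#' any non-override pathway that runs through it) unless at least one other
#' enzyme of an override pathway lies within the rule's gene-count window on
#' the same replicon — then the hit is attributed to the override pathway(s)
#' found. When no feature table is available for a genome the rule degrades
#' to whole-genome context and this is recorded in the `context_reason`.
#'
#' Hits for families without a context rule are unrestricted
#' (`allowed_monos` is `NA`): one protein may serve steps in any pathway
#' containing its family.
#'
#' @param resolved Output of [resolve_multi_profile()].
#' @param features Feature records from [read_feature_table()] (may cover
#'   several genomes); `NULL` for no neighbourhood information.
#' @param reg A `glyco_registry`.
#' @return `resolved` with list-column `allowed_monos` (character vector of
#'   monosaccharide ids, or `NA` meaning unrestricted) and `context_reason`.
#' @export
apply_context_rules <- function(resolved, features, reg) {
  resolved$allowed_monos <- rep(list(NA_character_), nrow(resolved))
  resolved$context_reason <- NA_character_
  rules <- reg$context_rules
  if (nrow(rules) == 0 || nrow(resolved) == 0) {
    return(resolved)
  }

  # mono -> union of families across its routes (computed once)
  all_monos <- reg$monosaccharides$mono_id
  fam_sets <- lapply(all_monos, function(m) mono_family_set(reg, m))
  names(fam_sets) <- all_monos

  for (r in seq_len(nrow(rules))) {
    gpe <- rules$gpe_id[r]
    window <- rules$window[r]
    overrides <- rules$overrides[[r]]
    containing <- all_monos[vapply(fam_sets, function(fs) gpe %in% fs, logical(1))]
    default_allowed <- setdiff(containing, overrides)
    # families that identify an override pathway, excluding the ambiguous one
    override_fams <- lapply(overrides, function(m) setdiff(fam_sets[[m]], gpe))
    names(override_fams) <- overrides

    targets <- which(resolved$resolved_gpe_id == gpe)
    for (i in targets) {
      g <- resolved$genome_id[i]
      neighbours <- context_neighbours(resolved, features, g, resolved$protein_id[i], window)
      found <- overrides[vapply(overrides, function(m) {
        length(intersect(override_fams[[m]], neighbours$fams)) > 0
      }, logical(1))]
      if (length(found)) {
        # an override attribution also covers pathways that are sub-routes
        # of the override pathway (its intermediates), provided they share
        # enzymes with it beyond the ambiguous family itself
        allowed <- context_override_allowed(found, containing, fam_sets, gpe)
        resolved$allowed_monos[[i]] <- allowed
        resolved$context_reason[i] <- paste0("override:", paste(sort_ids(found), collapse = ","), neighbours$tag)
      } else {
        resolved$allowed_monos[[i]] <- sort_ids(default_allowed)
        resolved$context_reason[i] <- paste0("default:", rules$default_pathway[r], neighbours$tag)
      }
    }
  }
  resolved
}

# monosaccharides covered by an override attribution: the overrides found
# plus any containing pathway whose family set sits inside a found
# override's set and shares non-ambiguous enzymes with it
context_override_allowed <- function(found, containing, fam_sets, ambiguous_fam) {
  allowed <- found
  for (m in setdiff(containing, found)) {
    for (o in found) {
      sub <- all(fam_sets[[m]] %in% fam_sets[[o]])
      shares <- length(intersect(fam_sets[[m]], setdiff(fam_sets[[o]], ambiguous_fam))) > 0
      if (sub && shares) {
        allowed <- c(allowed, m)
        break
      }
    }
  }
  sort_ids(allowed)
}

# resolved families of the proteins within +/- window genes of `protein` on
# its replicon; falls back to all resolved families of the genome when the
# genome has no feature records
context_neighbours <- function(resolved, features, genome, protein, window) {
  gres <- resolved[resolved$genome_id == genome, , drop = FALSE]
  feats <- if (is.null(features)) NULL else features[features$genome_id == genome, , drop = FALSE]
  if (is.null(feats) || nrow(feats) == 0) {
    return(list(fams = unique(gres$resolved_gpe_id[gres$protein_id != protein]), tag = " (whole-genome context)"))
  }
  self <- feats[feats$protein_id == protein, , drop = FALSE]
  if (nrow(self) == 0) {
    return(list(fams = unique(gres$resolved_gpe_id[gres$protein_id != protein]), tag = " (protein absent from feature table; whole-genome context)"))
  }
  near <- feats[feats$replicon_id == self$replicon_id[1] &
    abs(feats$ordinal_index - self$ordinal_index[1]) <= window &
    feats$protein_id != protein, , drop = FALSE]
  list(fams = unique(gres$resolved_gpe_id[gres$protein_id %in% near$protein_id]), tag = "")
}

#' Write the annotation-resolution audit trail
#'
#' One row per passing protein: candidate profiles, the winning annotation,
#' the rule that produced it, and any context attribution.
#'
#' @param resolved Output of [apply_context_rules()] (or
#'   [resolve_multi_profile()]).
#' @param path Output TSV path.
#' @export
write_resolution_audit <- function(resolved, path) {
  out <- resolved
  if ("allowed_monos" %in% names(out)) {
    out$allowed_monos <- vapply(out$allowed_monos, function(x) {
      if (length(x) == 1 && is.na(x)) "*" else paste(x, collapse = ",")
    }, "")
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
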