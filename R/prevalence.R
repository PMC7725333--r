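#' Per-monosaccharide prevalence across genomes
#'
#' @param mat Presence/absence matrix from [presence_matrix()] (genome_id
#'   plus one 0/1 column per monosaccharide).
#' @return A tibble: `mono_id`, `n_genomes_present`, `fraction`.
#' @export
prevalence <- function(mat) {
  monos <- setdiff(names(mat), "genome_id")
  n <- nrow(mat)
  tibble(
    mono_id = monos,
    n_genomes_present = vapply(monos, function(m) sum(mat[[m]]), integer(1)),
    fraction = vapply(monos, function(m) sum(mat[[m]]) / n, numeric(1))
  )
}

#' Classify monosaccharides into prevalence groups
#'
#' Groups follow the printed cutoffs: *common* when found in >= `hi` of
#' genomes, *rare* when found in <= `lo`, *less_common* in between. Both
#' boundaries are inclusive towards their own group.
#'
#' @param prev Tibble with `mono_id` and `fraction` columns (from
#'   [prevalence()]), or a named numeric vector of fractions.
#' @param hi,lo Group cutoffs as fractions (defaults 0.50 and 0.10).
#' @return A tibble: `mono_id`, `n_genomes_present` (if supplied),
#'   `fraction`, `group`.
#' @export
classify_groups <- function(prev, hi = 0.50, lo = 0.10) {
  if (hi <= lo) validation_error(paste0("group cutoffs require hi > lo (got hi=", hi, ", lo=", lo, ")"))
  if (is.numeric(prev)) {
    prev <- tibble(mono_id = names(prev) %||% as.character(seq_along(prev)), fraction = unname(prev))
  }
  if (any(prev$fraction < 0 | prev$fraction > 1)) input_error("fractions must lie in [0, 1]")
  prev$group <- ifelse(prev$fraction >= hi, "common",
    ifelse(prev$fraction <= lo, "rare", "less_common")
  )
  prev
}

alphabet_sizes <- function(alphabets) {
  tibble(
    genome_id = vapply(alphabets, function(ga) ga$genome_id, ""),
    alphabet_size = vapply(alphabets, alphabet_size, integer(1))
  )
}

join_taxonomy <- function(sizes, taxonomy) {
  out <- dplyr::left_join(sizes, taxonomy, by = "genome_id")
  out$species[is.na(out$species)] <- "unassigned"
  out
}

#' Best strain per species
#'
#' For species with several sequenced strains, reports the strain with the
#' largest alphabet (the value plotted in species-level comparisons).
#' Genomes without a taxonomy record are collected under species
#' `"unassigned"` rather than dropped.
#'
#' @param alphabets List of `glyco_alphabet` objects (or a tibble with
#'   `genome_id` and `alphabet_size`).
#' @param taxonomy Taxonomy tibble with `genome_id`, `species`, `genus`,
#'   `phylum` columns.
#' @return A tibble: `species`, `n_strains`, `max_size`, `best_genome`.
#' @export
species_aggregate <- function(alphabets, taxonomy) {
  sizes <- if (inherits(alphabets, "data.frame")) alphabets else alphabet_sizes(alphabets)
  joined <- join_taxonomy(sizes, taxonomy)
  joined |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(
      n_strains = dplyr::n(),
      max_size = max(.data$alphabet_size),
      best_genome = .data$genome_id[which.max(.data$alphabet_size)],
      .groups = "drop"
    )
}

#' Strain-level alphabet-size ranges per species
#'
#' Restricted to species with more than one sequenced strain and at least
#' one monosaccharide predicted in some strain.
#'
#' @inheritParams species_aggregate
#' @return A tibble: `species`, `n_strains`, `min_size`, `max_size`.
#' @export
strain_range <- function(alphabets, taxonomy) {
  sizes <- if (inherits(alphabets, "data.frame")) alphabets else alphabet_sizes(alphabets)
  joined <- join_taxonomy(sizes, taxonomy)
  joined |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(
      n_strains = dplyr::n(),
      min_size = min(.data$alphabet_size),
      max_size = max(.data$alphabet_size),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_strains > 1, .data$max_size >= 1)
}

#' Phylum-by-monosaccharide prevalence
#'
#' Fractions of genomes per phylum in which each monosaccharide is present.
#' Phyla with fewer than `min_genomes` sequenced genomes are excluded from
#' the rendered table but kept in the raw output.
#'
#' @param mat Presence/absence matrix from [presence_matrix()].
#' @param taxonomy Taxonomy tibble.
#' @param min_genomes Minimum genomes per phylum for the rendered table.
#' @return A list with `raw` (all phyla) and `rendered` (filtered) tibbles:
#'   `phylum`, `n_genomes`, then one fraction column per monosaccharide.
#' @export
phylum_prevalence <- function(mat, taxonomy, min_genomes = 5) {
  monos <- setdiff(names(mat), "genome_id")
  joined <- dplyr::left_join(mat, taxonomy[, c("genome_id", "phylum")], by = "genome_id")
  joined$phylum[is.na(joined$phylum)] <- "unassigned"
  raw <- joined |>
    dplyr::group_by(.data$phylum) |>
    dplyr::summarise(
      n_genomes = dplyr::n(),
      dplyr::across(dplyr::all_of(monos), mean),
      .groups = "drop"
    )
  list(raw = raw, rendered = raw[raw$n_genomes >= min_genomes, , drop = FALSE])
}

#' Genomes containing both members of monosaccharide pairs
#'
#' Counts genomes in which both members of each pair (e.g. enantiomeric
#' pairs, isomeric N-acetyl derivatives) are present, with a per-phylum
#' breakdown. A degenerate pair (X, X) counts genomes containing X.
#'
#' @param mat Presence/absence matrix.
#' @param taxonomy Taxonomy tibble.
#' @param pairs Tibble (or 2-column data frame) of monosaccharide id pairs.
#' @return A tibble: `mono_a`, `mono_b`, `n_genomes`, `phyla` (list-column
#'   of per-phylum counts).
#' @export
cooccurrence_pairs <- function(mat, taxonomy, pairs) {
  monos <- setdiff(names(mat), "genome_id")
  unknown <- setdiff(unique(c(pairs[[1]], pairs[[2]])), monos)
  if (length(unknown)) input_error(paste0("pairs reference unknown monosaccharides: ", paste(unknown, collapse = ", ")))
  phy <- taxonomy$phylum[match(mat$genome_id, taxonomy$genome_id)]
  phy[is.na(phy)] <- "unassigned"
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs[[1]][i]
    b <- pairs[[2]][i]
    both <- mat[[a]] == 1 & mat[[b]] == 1
    breakdown <- if (any(both)) {
      tab <- table(phy[both])
      tibble(phylum = names(tab), n = as.integer(tab))
    } else {
      tibble(phylum = character(), n = integer())
    }
    tibble(mono_a = a, mono_b = b, n_genomes = sum(both), phyla = list(breakdown))
  })
  dplyr::bind_rows(out)
}

#' Alphabet size versus proteome size
#'
#' Tests whether the number of monosaccharides a genome can make tracks its
#' proteome size, using the Spearman rank correlation with a seeded
#' permutation p-value.
#'
#' @param alphabets List of `glyco_alphabet` objects (or a sizes tibble).
#' @param taxonomy Taxonomy tibble with a `proteome_size` column.
#' @param n_perm Number of permutations.
#' @param seed Seed for the permutation null.
#' @return A list: `table` (genome_id, proteome_size, alphabet_size),
#'   `rho`, `p_value`.
#' @export
size_vs_proteome <- function(alphabets, taxonomy, n_perm = 10000, seed = 1) {
  sizes <- if (inherits(alphabets, "data.frame")) alphabets else alphabet_sizes(alphabets)
  joined <- dplyr::inner_join(sizes, taxonomy[, c("genome_id", "proteome_size")], by = "genome_id")
  if (!nrow(joined)) input_error("no genomes with both alphabet and proteome size")
  x <- joined$proteome_size
  y <- joined$alphabet_size
  rho <- if (stats::sd(x) == 0 || stats::sd(y) == 0) 0 else stats::cor(x, y, method = "spearman")
  set.seed(seed)
  null <- replicate(n_perm, {
    yp <- sample(y)
    if (stats::sd(x) == 0 || stats::sd(yp) == 0) 0 else stats::cor(x, yp, method = "spearman")
  })
  p <- (1 + sum(abs(null) >= abs(rho))) / (n_perm + 1)
  list(table = joined[, c("genome_id", "proteome_size", "alphabet_size")], rho = rho, p_value = p)
}

#' Histogram of alphabet sizes
#'
#' @param alphabets List of `glyco_alphabet` objects (or a sizes tibble).
#' @param by_species Optional taxonomy tibble; when supplied, one bar entry
#'   per species using the best strain (max size).
#' @return A ggplot object.
#' @export
plot_alphabet_histogram <- function(alphabets, by_species = NULL) {
  sizes <- if (inherits(alphabets, "data.frame")) alphabets else alphabet_sizes(alphabets)
  if (!is.null(by_species)) {
    agg <- species_aggregate(sizes, by_species)
    sizes <- tibble(alphabet_size = agg$max_size)
  }
  ggplot2::ggplot(sizes, ggplot2::aes(x = .data$alphabet_size)) +
    ggplot2::geom_histogram(binwidth = 1, boundary = -0.5, fill = "grey30") +
    ggplot2::scale_x_continuous(breaks = scales_breaks(sizes$alphabet_size)) +
    ggplot2::labs(x = "alphabet size (monosaccharides)", y = "count") +
    ggplot2::theme_minimal()
}

scales_breaks <- function(x) {
  m <- max(x, 0)
  if (m <= 12) 0:max(m, 1) else pretty(c(0, m))
}

#' Grouped prevalence bar chart
#'
#' @param groups Output of [classify_groups()].
#' @return A ggplot object.
#' @export
plot_prevalence_groups <- function(groups) {
  g <- groups[order(-groups$fraction), ]
  g$mono_id <- factor(g$mono_id, levels = g$mono_id)
  ggplot2::ggplot(g, ggplot2::aes(x = .data$mono_id, y = .data$fraction, fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = c(0.5, 0.1), linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = NULL, y = "fraction of genomes", fill = "group") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5, hjust = 1, size = 6))
}
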