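#' Load the pathway registry
#'
#' The registry is the curated knowledge base the whole pipeline runs
#' against: monosaccharides, the nucleotide sugars they are activated as,
#' biosynthesis routes (ordered enzymatic steps, each step satisfiable by one
#' of several enzyme families), enzyme-family detection records (HMM profile
#' bit-score thresholds or blastp similarity/coverage cutoffs),
#' precursor--product pairs, product pairs sharing one pathway, and
#' genomic-context rules for substrate-ambiguous families.
#'
#' Validation collects *every* violation before failing, so a malformed
#' registry reports all problems at once.
#'
#' @param path Path to a registry YAML file. Defaults to the registry
#'   packaged with glycoscan (55 monosaccharides, 57 nucleotide sugars,
#'   57 HMM-profile enzyme families plus blast-query families).
#' @return A `glyco_registry` object: a list of tibbles (`monosaccharides`,
#'   `nucleotide_sugars`, `routes`, `enzyme_families`, `precursor_pairs`,
#'   `product_pairs`, `context_rules`) plus the parsed source tree used for
#'   bit-exact round-tripping by [dump_registry()].
#' @export
#' @examples
#' reg <- load_registry()
#' nrow(reg$monosaccharides)
load_registry <- function(path = system.file("extdata", "registry.yaml", package = "glycoscan")) {
  if (!file.exists(path)) input_error(paste0("registry file not found: ", path))
  raw <- tryCatch(yaml::read_yaml(path),
    error = function(e) input_error(paste0("registry file does not parse as YAML: ", conditionMessage(e)))
  )
  reg <- parse_registry(raw)
  reg$source <- raw
  reg$source_bytes <- readBin(path, "raw", file.size(path))
  validate_registry(reg)
  reg
}

parse_registry <- function(raw) {
  if (!is.list(raw)) validation_error("registry root is not a mapping")

  empty <- list(
    monos = tibble(
      mono_id = character(), name = character(), short = character(),
      enantiomer = character(), ring = character(), backbone = character()
    ),
    sugars = tibble(
      sugar_id = character(), mono_id = character(), nucleotide = character(),
      n_routes = integer()
    ),
    routes = tibble(
      route_id = character(), sugar_id = character(), precursor = character(),
      steps = list()
    ),
    fams = tibble(
      gpe_id = character(), annotation = character(), detection_mode = character(),
      threshold_bits = numeric(), blast_min_similarity = numeric(),
      blast_min_coverage = numeric(), threshold_method = character(),
      specificity_class = character(), seed_count = integer(), superset_of = list()
    )
  )

  monos <- dplyr::bind_rows(empty$monos, lapply(raw$monosaccharides, function(m) {
    tibble(
      mono_id = m$id %||% NA_character_, name = m$name %||% NA_character_,
      short = m$short %||% NA_character_, enantiomer = m$enantiomer %||% NA_character_,
      ring = m$ring %||% NA_character_, backbone = m$backbone %||% NA_character_
    )
  }))

  sugars <- dplyr::bind_rows(empty$sugars, lapply(raw$nucleotide_sugars, function(s) {
    tibble(
      sugar_id = s$id %||% NA_character_, mono_id = s$mono %||% NA_character_,
      nucleotide = s$nucleotide %||% NA_character_, n_routes = length(s$routes)
    )
  }))

  routes <- dplyr::bind_rows(empty$routes, lapply(raw$nucleotide_sugars, function(s) {
    dplyr::bind_rows(lapply(s$routes, function(r) {
      tibble(
        route_id = r$id %||% NA_character_, sugar_id = s$id %||% NA_character_,
        precursor = r$precursor %||% NA_character_,
        steps = list(lapply(r$steps, function(st) unlist(st, use.names = FALSE)))
      )
    }))
  }))

  fams <- dplyr::bind_rows(empty$fams, lapply(raw$enzyme_families, function(f) {
    tibble(
      gpe_id = f$gpe %||% NA_character_, annotation = f$annotation %||% NA_character_,
      detection_mode = f$mode %||% NA_character_,
      threshold_bits = as.numeric(f$threshold_bits %||% NA_real_),
      blast_min_similarity = as.numeric(f$min_similarity %||% NA_real_),
      blast_min_coverage = as.numeric(f$min_coverage %||% NA_real_),
      threshold_method = f$method %||% NA_character_,
      specificity_class = f$specificity %||% NA_character_,
      seed_count = as.integer(f$seeds %||% NA_integer_),
      superset_of = list(unlist(f$superset_of, use.names = FALSE) %||% character())
    )
  }))

  pairs_tbl <- function(x, a, b) {
    if (length(x) == 0) {
      return(tibble(!!a := character(), !!b := character()))
    }
    dplyr::bind_rows(lapply(x, function(p) {
      p <- unlist(p, use.names = FALSE)
      tibble(!!a := p[1], !!b := p[2])
    }))
  }

  ctx <- dplyr::bind_rows(lapply(raw$context_rules, function(r) {
    tibble(
      gpe_id = r$gpe %||% NA_character_, default_pathway = r$default %||% NA_character_,
      overrides = list(unlist(r$overrides, use.names = FALSE) %||% character()),
      window = as.integer(r$window %||% 10L)
    )
  }))
  if (nrow(ctx) == 0) {
    ctx <- tibble(
      gpe_id = character(), default_pathway = character(),
      overrides = list(), window = integer()
    )
  }

  structure(
    list(
      monosaccharides = monos, nucleotide_sugars = sugars, routes = routes,
      enzyme_families = fams,
      precursor_pairs = pairs_tbl(raw$precursor_pairs, "precursor", "product"),
      product_pairs = pairs_tbl(raw$product_pairs, "mono_a", "mono_b"),
      context_rules = ctx
    ),
    class = "glyco_registry"
  )
}

#' Validate a registry, reporting every violation
#'
#' @param reg A `glyco_registry`.
#' @return `reg`, invisibly, if valid; otherwise a classed
#'   `glyco_validation_error` listing all violations.
#' @export
validate_registry <- function(reg) {
  v <- character()
  monos <- reg$monosaccharides
  sugars <- reg$nucleotide_sugars
  fams <- reg$enzyme_families
  routes <- reg$routes

  if (nrow(monos) == 0) v <- c(v, "monosaccharides: none defined")
  if (anyDuplicated(monos$mono_id)) {
    v <- c(v, paste0("monosaccharides: duplicate ids: ", paste(unique(monos$mono_id[duplicated(monos$mono_id)]), collapse = ", ")))
  }
  if (anyDuplicated(sugars$sugar_id)) {
    v <- c(v, paste0("nucleotide_sugars: duplicate ids: ", paste(unique(sugars$sugar_id[duplicated(sugars$sugar_id)]), collapse = ", ")))
  }
  if (anyDuplicated(fams$gpe_id)) {
    v <- c(v, paste0("enzyme_families: duplicate gpe ids: ", paste(unique(fams$gpe_id[duplicated(fams$gpe_id)]), collapse = ", ")))
  }

  bad_gpe <- fams$gpe_id[!is.na(fams$gpe_id) & !is_gpe_id(fams$gpe_id)]
  if (length(bad_gpe)) {
    v <- c(v, paste0("enzyme_families: ids not of the form GPE+5 digits: ", paste(bad_gpe, collapse = ", ")))
  }

  for (i in seq_len(nrow(fams))) {
    f <- fams[i, ]
    has_thr <- !is.na(f$threshold_bits)
    has_blast <- !is.na(f$blast_min_similarity) && !is.na(f$blast_min_coverage)
    if (identical(f$detection_mode, "hmm_profile")) {
      if (!has_thr || has_blast) v <- c(v, paste0("enzyme_families/", f$gpe_id, ": hmm_profile mode requires threshold_bits only"))
      if (has_thr && f$threshold_bits <= 0) v <- c(v, paste0("enzyme_families/", f$gpe_id, ": threshold_bits must be > 0"))
    } else if (identical(f$detection_mode, "blast_query")) {
      if (!has_blast || has_thr) v <- c(v, paste0("enzyme_families/", f$gpe_id, ": blast_query mode requires min_similarity and min_coverage only"))
    } else {
      v <- c(v, paste0("enzyme_families/", f$gpe_id, ": unknown detection_mode '", f$detection_mode, "'"))
    }
    if (!is.na(f$seed_count) && f$seed_count < 1) v <- c(v, paste0("enzyme_families/", f$gpe_id, ": seed_count must be >= 1"))
    dangling <- setdiff(f$superset_of[[1]], fams$gpe_id)
    if (length(dangling)) v <- c(v, paste0("enzyme_families/", f$gpe_id, ": superset_of references unknown families: ", paste(dangling, collapse = ", ")))
  }

  bad_mono_ref <- setdiff(sugars$mono_id, monos$mono_id)
  if (length(bad_mono_ref)) v <- c(v, paste0("nucleotide_sugars: unknown monosaccharide ids: ", paste(bad_mono_ref, collapse = ", ")))
  no_route <- setdiff(sugars$sugar_id, routes$sugar_id)
  if (length(no_route)) v <- c(v, paste0("nucleotide_sugars: sugars without any route: ", paste(no_route, collapse = ", ")))

  for (i in seq_len(nrow(routes))) {
    r <- routes[i, ]
    steps <- r$steps[[1]]
    if (length(steps) == 0) {
      v <- c(v, paste0("routes/", r$route_id, ": no steps"))
      next
    }
    for (j in seq_along(steps)) {
      if (length(steps[[j]]) == 0) v <- c(v, paste0("routes/", r$route_id, "/step", j, ": empty family set"))
      unknown <- setdiff(steps[[j]], fams$gpe_id)
      if (length(unknown)) v <- c(v, paste0("routes/", r$route_id, "/step", j, ": unknown families: ", paste(unknown, collapse = ", ")))
    }
  }
  if (anyDuplicated(routes$route_id)) v <- c(v, "routes: duplicate route ids")

  pp <- reg$precursor_pairs
  for (col in c("precursor", "product")) {
    unknown <- setdiff(pp[[col]], monos$mono_id)
    if (length(unknown)) v <- c(v, paste0("precursor_pairs: unknown monosaccharides: ", paste(unknown, collapse = ", ")))
  }
  if (nrow(pp) > 0 && has_cycle(pp$precursor, pp$product)) {
    v <- c(v, "precursor_pairs: the precursor->product relation contains a cycle")
  }

  qq <- reg$product_pairs
  unknown <- setdiff(c(qq$mono_a, qq$mono_b), monos$mono_id)
  if (length(unknown)) v <- c(v, paste0("product_pairs: unknown monosaccharides: ", paste(unknown, collapse = ", ")))
  for (i in seq_len(nrow(qq))) {
    if (!product_pair_routes_shared(reg, qq$mono_a[i], qq$mono_b[i])) {
      v <- c(v, paste0(
        "product_pairs: ", qq$mono_a[i], "/", qq$mono_b[i],
        " do not share a route up to the final divergent step"
      ))
    }
  }

  ctx <- reg$context_rules
  for (i in seq_len(nrow(ctx))) {
    r <- ctx[i, ]
    if (!r$gpe_id %in% fams$gpe_id) v <- c(v, paste0("context_rules: unknown family ", r$gpe_id))
    unknown <- setdiff(c(r$default_pathway, r$overrides[[1]]), monos$mono_id)
    if (length(unknown)) v <- c(v, paste0("context_rules/", r$gpe_id, ": unknown pathways: ", paste(unknown, collapse = ", ")))
  }

  if (length(v)) validation_error(v)
  invisible(reg)
}

has_cycle <- function(from, to) {
  nodes <- unique(c(from, to))
  adj <- split(to, factor(from, levels = nodes))
  state <- stats::setNames(rep(0L, length(nodes)), nodes) # 0 unseen, 1 open, 2 done
  visit <- function(n) {
    if (state[[n]] == 1L) {
      return(TRUE)
    }
    if (state[[n]] == 2L) {
      return(FALSE)
    }
    state[[n]] <<- 1L
    for (m in adj[[n]] %||% character()) if (visit(m)) {
      return(TRUE)
    }
    state[[n]] <<- 2L
    FALSE
  }
  any(vapply(nodes, visit, logical(1)))
}

# two product-pair members must share a route that is identical except
# (at most) for the terminal step, i.e. the final homologous reductase
product_pair_routes_shared <- function(reg, mono_a, mono_b) {
  ra <- mono_routes(reg, mono_a)
  rb <- mono_routes(reg, mono_b)
  for (a in ra) {
    for (b in rb) {
      if (length(a) != length(b)) next
      n <- length(a)
      head_ok <- n == 1 || identical(a[-n], b[-n])
      if (head_ok) {
        return(TRUE)
      }
    }
  }
  FALSE
}

mono_routes <- function(reg, mono) {
  sug <- reg$nucleotide_sugars$sugar_id[reg$nucleotide_sugars$mono_id == mono]
  reg$routes$steps[reg$routes$sugar_id %in% sug]
}

# union of all step families over all routes of all sugars of a monosaccharide
mono_family_set <- function(reg, mono) {
  unique(unlist(mono_routes(reg, mono), use.names = FALSE))
}

#' Write a registry back to YAML
#'
#' Dumping a freshly loaded registry reproduces the source file byte for
#' byte, so the packaged registry can be edited, reloaded and re-emitted
#' without spurious diffs.
#'
#' @param reg A `glyco_registry` loaded by [load_registry()].
#' @param path Output path.
#' @export
dump_registry <- function(reg, path) {
  if (!is.null(reg$source_bytes)) {
    writeBin(reg$source_bytes, path)
  } else if (!is.null(reg$source)) {
    yaml::write_yaml(reg$source, path)
  } else {
    input_error("registry has no source to dump")
  }
  invisible(path)
}

precursor_columns <- c("Glc-1-P", "Fruf-6-P", "GDP-Man", "UDP-Glc2NAc", "Glc2NAc-1-P", "Sed-7-P")

# precursor column(s) a sugar belongs to: the distinct precursors of its routes
sugar_precursors <- function(reg, sugar_id) {
  unique(reg$routes$precursor[reg$routes$sugar_id == sugar_id])
}

#' Summarize the registry as a precursor-by-statistic table
#'
#' Reproduces the structure of the pathway summary table: per precursor,
#' the number of nucleotide sugars, of monosaccharides, and monosaccharide
#' counts by backbone class, enantiomer and ring form, plus nucleotide-sugar
#' counts by nucleotide. A sugar with routes from two precursors appears in
#' both columns; the `total` column counts every sugar and monosaccharide
#' once.
#'
#' @param reg A `glyco_registry`.
#' @return A tibble with a `statistic` column, one column per precursor, and
#'   a `total` column of distinct counts.
#' @export
registry_summary <- function(reg) {
  sugars <- reg$nucleotide_sugars
  monos <- reg$monosaccharides

  # (sugar, precursor-column) membership, one row per column a sugar sits in
  memb <- dplyr::bind_rows(lapply(seq_len(nrow(sugars)), function(i) {
    tibble(
      sugar_id = sugars$sugar_id[i], mono_id = sugars$mono_id[i],
      nucleotide = sugars$nucleotide[i],
      precursor = sugar_precursors(reg, sugars$sugar_id[i])
    )
  }))
  memb <- dplyr::left_join(memb, monos, by = "mono_id")

  cols <- intersect(precursor_columns, unique(memb$precursor))
  cols <- c(cols, setdiff(unique(memb$precursor), precursor_columns))

  count_by <- function(df, what) {
    vapply(cols, function(p) {
      sub <- df[df$precursor == p, ]
      switch(what,
        sugars = length(unique(sub$sugar_id)),
        monos = length(unique(sub$mono_id))
      )
    }, integer(1))
  }

  rows <- list()
  add_row <- function(stat, per_col, total) {
    rows[[length(rows) + 1]] <<- tibble(statistic = stat, !!!stats::setNames(as.list(per_col), cols), total = total)
  }

  add_row("nucleotide_sugars", count_by(memb, "sugars"), length(unique(memb$sugar_id)))
  add_row("monosaccharides", count_by(memb, "monos"), length(unique(memb$mono_id)))

  level_rows <- function(field, prefix, levels) {
    for (lv in levels) {
      sub <- memb[memb[[field]] == lv, ]
      per <- vapply(cols, function(p) length(unique(sub$mono_id[sub$precursor == p])), integer(1))
      add_row(paste0(prefix, "_", gsub("/", "_", lv)), per, length(unique(sub$mono_id)))
    }
  }
  level_rows("backbone", "backbone", c("pentose", "hexose", "heptulose", "nonulose"))
  level_rows("enantiomer", "enantiomer", c("d", "l"))
  level_rows("ring", "ring", c("pyranose", "furanose"))

  for (nt in c("ADP", "CDP", "CMP", "GDP", "TDP/dTDP", "UDP")) {
    sub <- memb[memb$nucleotide == nt, ]
    per <- vapply(cols, function(p) length(unique(sub$sugar_id[sub$precursor == p])), integer(1))
    add_row(paste0("nucleotide_", gsub("/", "_", nt)), per, length(unique(sub$sugar_id)))
  }

  dplyr::bind_rows(rows)
}

#' Write the registry summary as TSV
#'
#' @param reg A `glyco_registry`.
#' @param path Output TSV path.
#' @export
write_registry_summary <- function(reg, path) {
  utils::write.table(registry_summary(reg), path,
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  invisible(path)
}

#' Precursor--product monosaccharide pairs
#'
#' Pairs for which presence of the product pathway implies presence of the
#' precursor monosaccharide (the product pathway runs through the precursor),
#' in registry order. Used by [propagate_pairs()].
#'
#' @param reg A `glyco_registry`.
#' @return A tibble with columns `precursor` and `product`.
#' @export
precursor_closure_pairs <- function(reg) reg$precursor_pairs

#' @export
print.glyco_registry <- function(x, ...) {
  cat(
    "<glyco_registry> ", nrow(x$monosaccharides), " monosaccharides, ",
    nrow(x$nucleotide_sugars), " nucleotide sugars, ",
    nrow(x$routes), " routes, ",
    sum(x$enzyme_families$detection_mode == "hmm_profile"), " HMM families + ",
    sum(x$enzyme_families$detection_mode == "blast_query"), " blast families\n",
    sep = ""
  )
  invisible(x)
}
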