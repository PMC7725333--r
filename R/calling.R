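#' Evaluate pathway completeness for one genome
#'
#' Applies the completeness rule: a route step is satisfied when at least
#' one attributed hit matches any enzyme family in the step's alternative
#' set (and, for context-restricted hits, the route's monosaccharide is
#' among the hit's allowed pathways); a route is complete when every step is
#' satisfied; a nucleotide sugar is made when at least one of its routes is
#' complete. Absence of a homologue for even one step means the
#' monosaccharide is not called.
#'
#' @param attributed Hits for one genome from [apply_context_rules()].
#' @param reg A `glyco_registry`.
#' @param genome_id Genome identifier (checked against the hits).
#' @return A tibble of step calls: `sugar_id`, `mono_id`, `route_id`,
#'   `step_index`, `satisfied`, `supporting` (list of protein ids).
#' @export
call_routes <- function(attributed, reg, genome_id) {
  h <- attributed[attributed$genome_id == genome_id, , drop = FALSE]
  restricted <- if (nrow(h)) {
    !vapply(h$allowed_monos %||% rep(list(NA_character_), nrow(h)), function(x) length(x) == 1 && is.na(x), logical(1))
  } else {
    logical()
  }
  if (!"allowed_monos" %in% names(h)) h$allowed_monos <- rep(list(NA_character_), nrow(h))

  # family -> row indices, computed once per genome
  by_fam <- split(seq_len(nrow(h)), h$resolved_gpe_id)

  routes <- reg$routes
  mono_of <- stats::setNames(reg$nucleotide_sugars$mono_id, reg$nucleotide_sugars$sugar_id)

  out <- vector("list", nrow(routes))
  for (i in seq_len(nrow(routes))) {
    steps <- routes$steps[[i]]
    sugar <- routes$sugar_id[i]
    mono <- mono_of[[sugar]]
    sat <- logical(length(steps))
    supp <- vector("list", length(steps))
    for (j in seq_along(steps)) {
      rows <- unlist(by_fam[steps[[j]]], use.names = FALSE)
      if (length(rows)) {
        ok <- vapply(rows, function(k) {
          !restricted[k] || mono %in% h$allowed_monos[[k]]
        }, logical(1))
        rows <- rows[ok]
      }
      sat[j] <- length(rows) > 0
      supp[[j]] <- sort_ids(unique(h$protein_id[rows]))
    }
    out[[i]] <- tibble(
      sugar_id = sugar, mono_id = mono, route_id = routes$route_id[i],
      step_index = seq_along(steps), satisfied = sat, supporting = supp
    )
  }
  dplyr::bind_rows(out)
}

#' Close route calls under product pairs and precursor propagation
#'
#' Builds the genome's glycan alphabet from step calls:
#'
#' * a monosaccharide is *detected* when some route of one of its
#'   nucleotide sugars is complete;
#' * product-pair members (two monosaccharides sharing one pathway up to a
#'   final homologous reductase) are marked present together;
#' * presence of a product monosaccharide marks its registered precursor
#'   present (the product pathway runs through the precursor), iterated to
#'   a fixed point.
#'
#' Monosaccharides added only by closure are tracked as *implied*, keeping
#' detected evidence distinguishable from propagated presence.
#'
#' @param calls Step calls from [call_routes()].
#' @param reg A `glyco_registry`.
#' @param genome_id Genome identifier stored on the result.
#' @return A `glyco_alphabet`: list with `genome_id`, `present`, `detected`,
#'   `implied` (character vectors of monosaccharide ids), `evidence` (the
#'   step calls) and `partial` (tibble of incomplete sugars and their
#'   missing-step counts).
#' @export
propagate_pairs <- function(calls, reg, genome_id = "genome") {
  pp <- reg$precursor_pairs
  if (nrow(pp) > 0 && has_cycle(pp$precursor, pp$product)) {
    validation_error("precursor_pairs contain a cycle; propagation requires an acyclic relation")
  }

  if (nrow(calls)) {
    route_ok <- calls |>
      dplyr::group_by(.data$sugar_id, .data$mono_id, .data$route_id) |>
      dplyr::summarise(
        complete = all(.data$satisfied), missing = sum(!.data$satisfied),
        n_steps = dplyr::n(), .groups = "drop"
      )
    detected <- sort_ids(unique(route_ok$mono_id[route_ok$complete]))
    # a pathway is "partial" when its best route has some but not all steps:
    # genomes with no enzyme of a pathway at all are plain absences
    sugar_ok <- route_ok |>
      dplyr::group_by(.data$sugar_id, .data$mono_id) |>
      dplyr::summarise(
        made = any(.data$complete),
        best_missing = min(.data$missing),
        best_total = .data$n_steps[which.min(.data$missing)][1],
        .groups = "drop"
      )
    partial <- sugar_ok[!sugar_ok$made & sugar_ok$best_missing < sugar_ok$best_total,
      c("sugar_id", "best_missing"),
      drop = FALSE
    ]
    names(partial) <- c("sugar_id", "missing_steps")
  } else {
    detected <- character()
    partial <- tibble(sugar_id = character(), missing_steps = integer())
  }

  present <- detected
  repeat {
    new <- present
    # product pairs: both members or neither
    for (i in seq_len(nrow(reg$product_pairs))) {
      a <- reg$product_pairs$mono_a[i]
      b <- reg$product_pairs$mono_b[i]
      if (a %in% new || b %in% new) new <- union(new, c(a, b))
    }
    # precursor propagation: product present => precursor present
    hit <- pp$product %in% new
    new <- union(new, pp$precursor[hit])
    if (setequal(new, present)) break
    present <- new
  }
  present <- sort_ids(unique(present))

  structure(
    list(
      genome_id = genome_id,
      present = present,
      detected = detected,
      implied = setdiff(present, detected),
      evidence = calls,
      partial = partial
    ),
    class = "glyco_alphabet"
  )
}

#' Alphabet size of a genome
#'
#' The number of distinct monosaccharides present, counting each
#' monosaccharide once however many nucleotide-sugar forms it has (l-Rha
#' reached via UDP and TDP/dTDP routes is one letter).
#'
#' @param ga A `glyco_alphabet`.
#' @return Integer count.
#' @export
alphabet_size <- function(ga) length(unique(ga$present))

#' @export
print.glyco_alphabet <- function(x, ...) {
  cat("<glyco_alphabet> ", x$genome_id, ": ", alphabet_size(x), " monosaccharides (",
    length(x$detected), " detected, ", length(x$implied), " implied)\n",
    sep = ""
  )
  invisible(x)
}

#' Presence/absence matrix across genomes
#'
#' @param alphabets List of `glyco_alphabet` objects.
#' @param reg A `glyco_registry` (fixes column order to registry order).
#' @return A tibble: `genome_id` plus one 0/1 column per monosaccharide.
#' @export
presence_matrix <- function(alphabets, reg) {
  monos <- reg$monosaccharides$mono_id
  rows <- lapply(alphabets, function(ga) {
    tibble(genome_id = ga$genome_id, !!!stats::setNames(as.list(as.integer(monos %in% ga$present)), monos))
  })
  dplyr::bind_rows(rows)
}

#' Write the presence/absence matrix as TSV
#'
#' @param mat Tibble from [presence_matrix()].
#' @param path Output path.
#' @export
write_presence_matrix <- function(mat, path) {
  utils::write.table(mat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write per-genome evidence bundles as JSON
#'
#' One object per genome: present/detected/implied monosaccharides, partial
#' pathways with missing-step counts, and per-route step satisfaction.
#'
#' @param alphabets List of `glyco_alphabet` objects.
#' @param path Output JSON path.
#' @export
write_evidence_json <- function(alphabets, path) {
  bundle <- lapply(alphabets, function(ga) {
    ev <- ga$evidence
    routes <- if (nrow(ev)) {
      ev |>
        dplyr::group_by(.data$sugar_id, .data$route_id) |>
        dplyr::summarise(
          complete = all(.data$satisfied),
          steps = list(stats::setNames(.data$satisfied, paste0("step", .data$step_index))),
          .groups = "drop"
        )
    } else {
      NULL
    }
    list(
      genome_id = ga$genome_id,
      present = as.list(ga$present),
      detected = as.list(ga$detected),
      implied = as.list(ga$implied),
      partial = if (nrow(ga$partial)) {
        stats::setNames(as.list(ga$partial$missing_steps), ga$partial$sugar_id)
      } else {
        stats::setNames(list(), character())
      },
      routes = if (!is.null(routes)) {
        stats::setNames(lapply(seq_len(nrow(routes)), function(i) {
          list(complete = routes$complete[i], steps = as.list(routes$steps[[i]]))
        }), routes$route_id)
      } else {
        stats::setNames(list(), character())
      }
    )
  })
  names(bundle) <- vapply(alphabets, function(ga) ga$genome_id, "")
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' End-to-end call for one genome
#'
#' Convenience wrapper: threshold filtering, multi-profile resolution,
#' context attribution, completeness calling and pair/precursor closure.
#'
#' @param hmm_hits,blast_hits Raw hit tibbles for the genome (either may be
#'   `NULL`).
#' @param features Feature records for the genome, or `NULL`.
#' @param reg A `glyco_registry`.
#' @param genome_id Genome identifier.
#' @return A `glyco_alphabet`.
#' @export
call_genome <- function(hmm_hits, blast_hits, features, reg, genome_id) {
  parts <- list()
  if (!is.null(hmm_hits) && nrow(hmm_hits)) parts <- c(parts, list(filter_hmm_hits(hmm_hits, reg)))
  if (!is.null(blast_hits) && nrow(blast_hits)) parts <- c(parts, list(filter_blast_hits(blast_hits, reg)))
  hits <- if (length(parts)) dplyr::bind_rows(parts) else tibble(passes_threshold = logical())
  resolved <- resolve_multi_profile(hits, reg)
  attributed <- apply_context_rules(resolved, features, reg)
  calls <- call_routes(attributed, reg, genome_id)
  propagate_pairs(calls, reg, genome_id)
}
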