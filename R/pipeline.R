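#' Filter, resolve and attribute hits for a set of genomes
#'
#' @param hmm_hits,blast_hits Raw hit tibbles (any number of genomes; either
#'   may be `NULL` or empty).
#' @param features Feature records covering the genomes, or `NULL`.
#' @param reg A `glyco_registry`.
#' @return Attributed hits: one row per passing protein with
#'   `resolved_gpe_id`, `resolution_reason`, `allowed_monos`,
#'   `context_reason`.
#' @export
scan_hits <- function(hmm_hits, blast_hits, features, reg) {
  parts <- list()
  if (!is.null(hmm_hits) && nrow(hmm_hits)) parts <- c(parts, list(filter_hmm_hits(hmm_hits, reg)))
  if (!is.null(blast_hits) && nrow(blast_hits)) parts <- c(parts, list(filter_blast_hits(blast_hits, reg)))
  if (!length(parts)) {
    resolved <- resolve_multi_profile(
      tibble(
        genome_id = character(), protein_id = character(), gpe_id = character(),
        passes_threshold = logical()
      ), reg
    )
    return(apply_context_rules(resolved, features, reg))
  }
  hits <- dplyr::bind_rows(parts)
  resolved <- resolve_multi_profile(hits, reg)
  apply_context_rules(resolved, features, reg)
}

#' Call glycan alphabets for every genome in a universe
#'
#' @param attributed Attributed hits from [scan_hits()].
#' @param reg A `glyco_registry`.
#' @param genome_ids Genomes to call (defaults to those present in the
#'   hits; pass the full taxonomy list to include hit-less genomes, which
#'   receive empty alphabets).
#' @return Named list of `glyco_alphabet` objects.
#' @export
call_alphabets <- function(attributed, reg, genome_ids = unique(attributed$genome_id)) {
  out <- lapply(genome_ids, function(gid) {
    calls <- call_routes(attributed, reg, gid)
    propagate_pairs(calls, reg, gid)
  })
  names(out) <- genome_ids
  out
}

#' Run the full pipeline on an in-memory or on-disk universe
#'
#' @param universe A `glyco_universe` (from [generate_universe()]) or a
#'   directory path (read with [read_universe()]).
#' @param reg A `glyco_registry`.
#' @return A list: `attributed` hits, `alphabets` (named list), `matrix`
#'   (presence/absence tibble), `taxonomy`.
#' @export
run_pipeline <- function(universe, reg) {
  if (is.character(universe)) universe <- read_universe(universe)
  attributed <- scan_hits(universe$hmm_hits, universe$blast_hits, universe$features, reg)
  alphabets <- call_alphabets(attributed, reg, genome_ids = universe$taxonomy$genome_id)
  list(
    attributed = attributed,
    alphabets = alphabets,
    matrix = presence_matrix(alphabets, reg),
    taxonomy = universe$taxonomy
  )
}
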