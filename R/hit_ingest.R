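#' Read a HMMER3 per-sequence or per-domain hit table
#'
#' Parses `hmmsearch --tblout` or `--domtblout` output into one hit per
#' (protein, profile) pair. Thresholding downstream uses the best-one-domain
#' bit score, which is independent of database size; duplicate rows for the
#' same pair keep the maximum best-one-domain score.
#'
#' @param path Path to the table.
#' @param dialect `"tblout"` (per sequence) or `"domtblout"` (per domain).
#' @param genome_id Genome the proteome belongs to; defaults to the file
#'   name stem.
#' @return A tibble of hits: `genome_id`, `protein_id`, `gpe_id`,
#'   `full_bits`, `best1dom_bits`, `evalue`.
#' @export
read_hmmer_table <- function(path, dialect = c("tblout", "domtblout"),
                             genome_id = strip_ext(basename(path))) {
  dialect <- tryCatch(match.arg(dialect), error = function(e) {
    input_error(paste0("unknown HMMER dialect: ", dialect[1]))
  })
  if (!file.exists(path)) input_error(paste0("HMMER table not found: ", path))
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  min_fields <- if (dialect == "tblout") 18L else 22L
  rows <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(rows) < min_fields)
  if (length(bad)) {
    input_error(paste0(
      "truncated ", dialect, " row(s) in ", path, " at line(s): ",
      paste(utils::head(bad, 10), collapse = ", ")
    ))
  }
  if (length(rows) == 0) {
    return(tibble(
      genome_id = character(), protein_id = character(), gpe_id = character(),
      full_bits = numeric(), best1dom_bits = numeric(), evalue = numeric()
    ))
  }
  field <- function(i) vapply(rows, `[[`, "", i)
  if (dialect == "tblout") {
    hits <- tibble(
      genome_id = genome_id,
      protein_id = field(1), gpe_id = field(3),
      full_bits = as.numeric(field(6)),
      best1dom_bits = as.numeric(field(9)),
      evalue = as.numeric(field(5))
    )
  } else {
    # per-domain rows: best-one-domain score is the max single-domain score
    hits <- tibble(
      genome_id = genome_id,
      protein_id = field(1), gpe_id = field(4),
      full_bits = as.numeric(field(8)),
      best1dom_bits = as.numeric(field(14)),
      evalue = as.numeric(field(7))
    )
  }
  hits |>
    dplyr::group_by(.data$genome_id, .data$protein_id, .data$gpe_id) |>
    dplyr::summarise(
      full_bits = max(.data$full_bits),
      best1dom_bits = max(.data$best1dom_bits),
      evalue = min(.data$evalue),
      .groups = "drop"
    )
}

strip_ext <- function(x) sub("\\.[A-Za-z0-9_]+$", "", x)

#' Read a BLAST tabular (outfmt 6 style) hit table
#'
#' Columns are declared explicitly because outfmt 6 is user-configurable.
#' Coverage is computed on the query (the characterized enzyme) as
#' `100 * length / qlen` unless a `qcovs` column is declared, in which case
#' that value is used verbatim. Similarity is the percentage of positives.
#' Multiple HSPs per (query, subject) pair keep the single highest-scoring
#' row.
#'
#' @param path Path to the table.
#' @param columns Character vector naming the columns in file order. Must
#'   include `qseqid`, `sseqid`, `ppos`, and either `qcovs` or both `length`
#'   and `qlen`.
#' @param genome_id Genome id; defaults to the file name stem.
#' @return A tibble of hits: `genome_id`, `protein_id`, `gpe_id`,
#'   `similarity_pct`, `coverage_pct`, `evalue` (NA if not declared).
#' @export
read_blast_table <- function(path,
                             columns = c("qseqid", "sseqid", "pident", "ppos", "length", "qlen", "evalue", "bitscore"),
                             genome_id = strip_ext(basename(path))) {
  if (!file.exists(path)) input_error(paste0("BLAST table not found: ", path))
  required <- c("qseqid", "sseqid", "ppos")
  missing <- setdiff(required, columns)
  if (length(missing)) input_error(paste0("BLAST column declaration is missing: ", paste(missing, collapse = ", ")))
  has_cov <- "qcovs" %in% columns
  if (!has_cov && !all(c("length", "qlen") %in% columns)) {
    input_error("BLAST column declaration needs either qcovs or both length and qlen")
  }
  df <- utils::read.table(path,
    sep = "\t", header = FALSE, comment.char = "#",
    col.names = columns, stringsAsFactors = FALSE, fill = FALSE
  )
  if (nrow(df) == 0) {
    return(tibble(
      genome_id = character(), protein_id = character(), gpe_id = character(),
      similarity_pct = numeric(), coverage_pct = numeric(), evalue = numeric()
    ))
  }
  cov <- if (has_cov) {
    as.numeric(df$qcovs)
  } else {
    100 * as.numeric(df$length) / as.numeric(df$qlen)
  }
  if (any(cov > 100)) {
    warning("query coverage > 100% in ", sum(cov > 100), " row(s); clamping to 100", call. = FALSE)
    cov <- pmin(cov, 100)
  }
  # query ids are either bare GPE ids or "GPExxxxx_<seed accession>"
  gpe_id <- ifelse(grepl("^GPE[0-9]{5}", df$qseqid), substr(df$qseqid, 1, 8), as.character(df$qseqid))
  hits <- tibble(
    genome_id = genome_id,
    protein_id = as.character(df$sseqid),
    gpe_id = gpe_id,
    similarity_pct = as.numeric(df$ppos),
    coverage_pct = cov,
    evalue = if ("evalue" %in% columns) as.numeric(df$evalue) else NA_real_,
    score = if ("bitscore" %in% columns) as.numeric(df$bitscore) else as.numeric(df$ppos)
  )
  hits |>
    dplyr::group_by(.data$genome_id, .data$protein_id, .data$gpe_id) |>
    dplyr::slice_max(.data$score, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select(-"score")
}

#' Apply HMM bit-score thresholds
#'
#' A hit passes when its best-one-domain bit score is greater than or equal
#' to the family's calibrated threshold (the comparison is inclusive).
#'
#' @param hits Tibble from [read_hmmer_table()].
#' @param reg A `glyco_registry`.
#' @return `hits` with a logical `passes_threshold` column.
#' @export
filter_hmm_hits <- function(hits, reg) {
  fams <- reg$enzyme_families
  idx <- match(hits$gpe_id, fams$gpe_id)
  if (anyNA(idx)) {
    input_error(paste0(
      "hits against unregistered profiles: ",
      paste(unique(hits$gpe_id[is.na(idx)]), collapse = ", ")
    ))
  }
  wrong_mode <- fams$detection_mode[idx] != "hmm_profile"
  if (any(wrong_mode)) {
    input_error(paste0(
      "HMM hits against non-HMM families: ",
      paste(unique(hits$gpe_id[wrong_mode]), collapse = ", ")
    ))
  }
  hits$passes_threshold <- hits$best1dom_bits >= fams$threshold_bits[idx]
  hits
}

#' Apply blastp similarity and coverage cutoffs
#'
#' A hit passes when both query coverage and sequence similarity meet the
#' family's cutoffs (defaults 90% coverage, 30% similarity; per-family
#' upward revisions are stored in the registry).
#'
#' @param hits Tibble from [read_blast_table()].
#' @param reg A `glyco_registry`.
#' @return `hits` with a logical `passes_threshold` column.
#' @export
filter_blast_hits <- function(hits, reg) {
  fams <- reg$enzyme_families
  idx <- match(hits$gpe_id, fams$gpe_id)
  if (anyNA(idx)) {
    input_error(paste0(
      "hits against unregistered blast queries: ",
      paste(unique(hits$gpe_id[is.na(idx)]), collapse = ", ")
    ))
  }
  wrong_mode <- fams$detection_mode[idx] != "blast_query"
  if (any(wrong_mode)) {
    input_error(paste0(
      "blast hits against non-blast families: ",
      paste(unique(hits$gpe_id[wrong_mode]), collapse = ", ")
    ))
  }
  hits$passes_threshold <- hits$coverage_pct >= fams$blast_min_coverage[idx] &
    hits$similarity_pct >= fams$blast_min_similarity[idx]
  hits
}

#' Read an NCBI assembly feature table
#'
#' Keeps CDS rows only and assigns each protein an ordinal gene-order index
#' per replicon by genomic start coordinate. The index is what the
#' genomic-context rules measure neighbourhood distance in.
#'
#' @param path Path to a `*_feature_table.txt` file (tab separated).
#' @param genome_id Genome id; defaults to the file name stem.
#' @return A tibble: `genome_id`, `protein_id`, `replicon_id`,
#'   `ordinal_index`, `strand`.
#' @export
read_feature_table <- function(path, genome_id = sub("_feature_table.*$", "", basename(path))) {
  if (!file.exists(path)) input_error(paste0("feature table not found: ", path))
  header <- readLines(path, n = 1)
  cols <- strsplit(sub("^#\\s*", "", header), "\t")[[1]]
  expected <- c("feature", "class", "genomic_accession", "start", "end", "strand", "product_accession")
  missing <- setdiff(expected, cols)
  if (length(missing)) {
    input_error(paste0(
      "feature table header is missing column(s): ", paste(missing, collapse = ", "),
      " (expected NCBI feature_table.txt dialect)"
    ))
  }
  df <- utils::read.table(path,
    sep = "\t", header = FALSE, skip = 1, quote = "",
    col.names = make.names(cols), stringsAsFactors = FALSE, fill = TRUE
  )
  names(df)[match(make.names(expected), names(df))] <- expected
  cds <- df[df$feature == "CDS", , drop = FALSE]
  if (nrow(cds) == 0) {
    return(tibble(
      genome_id = character(), protein_id = character(),
      replicon_id = character(), ordinal_index = integer(), strand = character()
    ))
  }
  cds <- cds[order(cds$genomic_accession, as.integer(cds$start), method = "radix"), ]
  ord <- stats::ave(seq_len(nrow(cds)), cds$genomic_accession, FUN = seq_along)
  tibble(
    genome_id = genome_id,
    protein_id = as.character(cds$product_accession),
    replicon_id = as.character(cds$genomic_accession),
    ordinal_index = as.integer(ord),
    strand = as.character(cds$strand)
  )
}
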