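# Tabular input/output and report writing.
#
# All interchange formats are plain text: TSV for mitotype tables,
# observations, pedigrees and quantification records; JSON for reports;
# optional FASTA export for unambiguous haplotypes.

range_from_code <- function(code) {
  switch(toupper(code),
         CR = control_region(),
         FULL = full_genome(),
         stop("unknown range code: ", code, " (use CR or FULL)"))
}

#' Read a mitotype table
#'
#' TSV with columns `sample_id`, `range` (`CR` for the control region
#' 16024-576 or `FULL` for the whole mitogenome), `mitotype_string`.
#'
#' @param path TSV file path.
#' @return Named list of [mitotype()]s keyed by `sample_id`.
#' @export
read_mitotype_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("sample_id", "range", "mitotype_string")
  if (!all(need %in% names(df)))
    stop("mitotype table needs columns ", paste(need, collapse = ", "))
  out <- lapply(seq_len(nrow(df)), function(i)
    parse_mitotype(df$mitotype_string[i], range_from_code(df$range[i]),
                   label = df$sample_id[i]))
  stats::setNames(out, df$sample_id)
}

#' Write a mitotype table
#'
#' @param mitotypes named list of [mitotype()]s.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_mitotype_table <- function(mitotypes, path) {
  range_code <- vapply(mitotypes, function(m) {
    if (range_identical(m$range, full_genome())) "FULL" else "CR"
  }, "")
  df <- data.frame(sample_id = names(mitotypes), range = range_code,
                   mitotype_string = vapply(mitotypes, serialize_mitotype, ""),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an observation table from TSV
#' @param path TSV with the [observation_table()] columns.
#' @return An [observation_table()].
#' @export
read_observations <- function(path) {
  observation_table(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Write an observation table to TSV
#' @param obs an [observation_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(obs, path) {
  utils::write.table(as.data.frame(obs), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a pedigree from PED-like TSV
#'
#' Columns `id`, `father`, `mother`, `sex`, `status`; empty string for
#' missing parents.
#'
#' @param path TSV path.
#' @return A [pedigree()].
#' @export
read_pedigree <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = NULL)
  pedigree(df)
}

#' Write a pedigree to PED-like TSV
#' @param p a [pedigree()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(p, path) {
  utils::write.table(as.data.frame(p), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export unambiguous mitotypes as FASTA
#'
#' @param mitotypes named list of unambiguous [mitotype()]s.
#' @param path output FASTA path.
#' @param reference reference sequence (see [mt_reference()]).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(mitotypes, path, reference = mt_reference()) {
  lines <- unlist(lapply(names(mitotypes), function(id) {
    seq <- apply_to_reference(mitotypes[[id]], reference)
    c(paste0(">", id),
      substring(seq, seq(1, nchar(seq), 70),
                pmin(seq(70, nchar(seq) + 69, 70), nchar(seq))))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Run the full inference chain on a dataset
#'
#' Executes deconvolution of the reference individual's mixed call,
#' haplogroup assignment of both components, tissue-contrast source
#' classification, pedigree segregation and matriline checks, and (when
#' quantification records are present) copy-number and insert-size
#' estimation, returning one structured report.
#'
#' @param dataset list with elements `pedigree` ([pedigree()]),
#'   `observations` ([observation_table()]), `mixed_call` (a mixed
#'   [mitotype()]) or `mitotypes` (named list containing per-individual
#'   calls from which the first mixed one is taken), optionally
#'   `true_mitotypes` (named list for the matriline check) and
#'   `quant_ratios` (numeric replicate ratios for copy estimation).
#' @param motifs a [motif_table()] (default [family_motif_table()]).
#' @param params list of tuning parameters: `hotspot_mask`,
#'   `min_anucleate`, `anucleate_mixed_tolerance`, `ploidy`.
#' @return List of class `pipeline_report`.
#' @export
run_pipeline <- function(dataset, motifs = family_motif_table(),
                         params = list()) {
  par <- utils::modifyList(
    list(hotspot_mask = default_hotspot_mask(), min_anucleate = 10L,
         anucleate_mixed_tolerance = 0.05, ploidy = 2L), params)
  mixed <- dataset$mixed_call
  if (is.null(mixed) && !is.null(dataset$mitotypes)) {
    amb <- Filter(Negate(is_unambiguous), dataset$mitotypes)
    if (length(amb)) mixed <- amb[[1]]
  }
  if (is.null(mixed)) stop("dataset carries no mixed mitotype to deconvolve")
  dec <- deconvolve_two_source(mixed, motifs, par$hotspot_mask)
  src <- classify_minor_source(dataset$observations, par$min_anucleate,
                               par$anucleate_mixed_tolerance)
  seg <- check_segregation(dataset$pedigree)
  mat <- if (!is.null(dataset$true_mitotypes))
    check_matriline(dataset$pedigree, dataset$true_mitotypes) else NULL
  cn <- if (!is.null(dataset$quant_ratios) && length(dataset$quant_ratios))
    aggregate_copies(dataset$quant_ratios, par$ploidy) else NULL
  structure(list(
    verdict = src$verdict,
    deconvolution = list(
      component_a = serialize_mitotype(dec$component_a),
      component_b = serialize_mitotype(dec$component_b),
      hg_a = dec$hg_a$haplogroup, hg_b = dec$hg_b$haplogroup,
      score_a = dec$hg_a$score, score_b = dec$hg_b$score,
      n_ambiguous = dec$n_ambiguous),
    source_call = src,
    segregation = seg,
    matriline_violations = if (is.null(mat)) NA_integer_ else nrow(mat),
    copy_estimate = if (is.null(cn)) NULL else
      list(copies_per_numt = cn$copies_per_numt, sd = cn$sd, n = cn$n,
           insert_size_bp = insert_size(cn$copies_per_numt)),
    params = par), class = "pipeline_report")
}

#' Write a pipeline report as JSON
#'
#' @param report a `pipeline_report` from [run_pipeline()] (or any
#'   list-like report).
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  clean <- rapply(unclass(report), function(x) {
    if (is.data.frame(x)) x else x
  }, how = "replace")
  jsonlite::write_json(clean, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", force = TRUE, pretty = TRUE)
  invisible(path)
}
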