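# Tissue-contrast evidence integration and pedigree segregation checks.
#
# The discriminating observation behind NUMT-versus-heteroplasmy calls:
# anucleate cells (thrombocytes, hair shafts) carry mtDNA but no intact
# nuclear genome, while mtDNA-depleted (rho-zero) cells carry only the
# nuclear genome. A minor component that vanishes from anucleate cells
# and is the sole signal in mtDNA-depleted cells is nuclear in origin.

TISSUE_CELL_CLASS <- c(
  blood = "nucleated", buccal = "nucleated", bone = "nucleated",
  intestinal = "nucleated", hair_root = "nucleated", pbmc = "nucleated",
  other = "nucleated",
  thrombocyte = "anucleate", hair_shaft = "anucleate",
  rho0_fibroblast = "mtDNA_depleted",
  blank = "control"
)

OBS_CALLS <- c("major_only", "minor_only", "mixed", "none")
OBS_ASSAYS <- c("direct_sanger", "clone", "single_cell", "mps")

#' Build a validated observation table
#'
#' One row per sample/cell/clone batch: who, which tissue, which assay,
#' what was called, and how many observations the row stands for. The
#' cell class is filled from a fixed tissue lookup (thrombocytes and
#' hair shafts are anucleate; rho-zero fibroblasts are mtDNA-depleted;
#' `blank` rows are negative controls; everything else is nucleated).
#'
#' @param df data frame with columns `individual_id`, `tissue`, `assay`,
#'   `call`, and optionally `n` (batch size, default 1).
#' @return The validated data frame with a `cell_class` column, class
#'   `observation_table`.
#' @export
observation_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("individual_id", "tissue", "assay", "call")
  if (!all(need %in% names(df)))
    stop("observations need columns ", paste(need, collapse = ", "))
  if (is.null(df$n)) df$n <- 1L
  df$n <- as.integer(df$n)
  if (any(is.na(df$n) | df$n < 1)) stop("n must be a positive count")
  bad_tissue <- !df$tissue %in% names(TISSUE_CELL_CLASS)
  if (any(bad_tissue)) stop("unknown tissue: ", df$tissue[bad_tissue][1])
  if (any(!df$call %in% OBS_CALLS))
    stop("call must be one of ", paste(OBS_CALLS, collapse = ", "))
  if (any(!df$assay %in% OBS_ASSAYS))
    stop("assay must be one of ", paste(OBS_ASSAYS, collapse = ", "))
  df$cell_class <- unname(TISSUE_CELL_CLASS[df$tissue])
  class(df) <- c("observation_table", "data.frame")
  df
}

#' Classify the source of a minor mitotype component
#'
#' Applies an ordered rule table to tissue-contrast observations:
#' \describe{
#'   \item{R0}{any negative-control (`blank`) row with a call other
#'     than `none` suspends interpretation: `CONTAMINATION_SUSPECTED`.}
#'   \item{R1}{nucleated tissues show the mixture, enough anucleate
#'     observations exist (`min_anucleate`), the minor component is
#'     (essentially) absent from them -- at most
#'     `anucleate_mixed_tolerance` of anucleate observations mixed or
#'     minor, a tolerance that absorbs the occasional hair shaft with
#'     nuclear remnants -- and any mtDNA-depleted cells show the minor
#'     component exclusively: `NUCLEAR_NUMT`.}
#'   \item{R2}{the minor component appears in anucleate cells above
#'     tolerance: `MT_HETEROPLASMY` (mitochondrial in origin; true
#'     heteroplasmy and paternal leakage are confounded at this level).}
#'   \item{otherwise}{`INCONCLUSIVE`.}
#' }
#'
#' @param obs an [observation_table()] (or data frame coercible to one)
#'   with at least one nucleated observation.
#' @param min_anucleate minimum anucleate observations required before
#'   their negativity counts (default 10).
#' @param anucleate_mixed_tolerance maximum tolerated fraction of
#'   anucleate observations showing the minor component (default 0.05).
#' @return List of class `source_call`: `verdict`, `evidence` (data
#'   frame of rule evaluations with counts), `note`.
#' @export
classify_minor_source <- function(obs, min_anucleate = 10L,
                                  anucleate_mixed_tolerance = 0.05) {
  if (!inherits(obs, "observation_table")) obs <- observation_table(obs)
  if (nrow(obs) < 1) stop("need at least one observation")
  n_by <- function(rows) sum(obs$n[rows])

  blank_pos <- n_by(obs$cell_class == "control" & obs$call != "none")
  nucleated <- obs$cell_class == "nucleated"
  if (!any(nucleated)) stop("no nucleated observations: cannot classify")
  nuc_mixed <- n_by(nucleated & obs$call %in% c("mixed", "minor_only"))
  anuc <- obs$cell_class == "anucleate"
  anuc_total <- n_by(anuc)
  anuc_minor <- n_by(anuc & obs$call %in% c("mixed", "minor_only"))
  anuc_frac <- if (anuc_total > 0) anuc_minor / anuc_total else NA_real_
  depl <- obs$cell_class == "mtDNA_depleted"
  depl_total <- n_by(depl)
  depl_minor_only <- n_by(depl & obs$call == "minor_only")

  evidence <- data.frame(
    rule = c("blank_negative", "nucleated_mixture_present",
             "anucleate_sample_size", "anucleate_minor_fraction",
             "depleted_minor_only"),
    satisfied = c(blank_pos == 0, nuc_mixed > 0,
                  anuc_total >= min_anucleate,
                  !is.na(anuc_frac) && anuc_frac <= anucleate_mixed_tolerance,
                  depl_total == 0 || depl_minor_only == depl_total),
    count = c(blank_pos, nuc_mixed, anuc_total, anuc_minor, depl_minor_only),
    total = c(n_by(obs$cell_class == "control"), n_by(nucleated),
              anuc_total, anuc_total, depl_total),
    stringsAsFactors = FALSE)

  verdict <- if (blank_pos > 0) "CONTAMINATION_SUSPECTED"
    else if (nuc_mixed > 0 && anuc_total >= min_anucleate &&
             anuc_frac <= anucleate_mixed_tolerance &&
             (depl_total == 0 || depl_minor_only == depl_total))
      "NUCLEAR_NUMT"
    else if (anuc_total > 0 && anuc_frac > anucleate_mixed_tolerance)
      "MT_HETEROPLASMY"
    else "INCONCLUSIVE"

  note <- if (verdict == "MT_HETEROPLASMY")
    "mitochondrial in origin; heteroplasmy vs paternal leakage not distinguished"
    else ""
  structure(list(verdict = verdict, evidence = evidence, note = note),
            class = "source_call")
}

#' @export
print.source_call <- function(x, ...) {
  cat("verdict:", x$verdict, "\n")
  print(x$evidence, row.names = FALSE)
  if (nzchar(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

#' Build a validated pedigree
#'
#' @param df data frame with columns `id`, `father`, `mother` (empty or
#'   NA for founders), `sex` (`"M"`/`"F"`/`""`), and `status` (carrier
#'   status of the insertion allele: `carrier`, `non_carrier`,
#'   `unknown`).
#' @return The validated data frame, class `pedigree`.
#' @export
pedigree <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("id", "father", "mother", "sex", "status")
  if (!all(need %in% names(df)))
    stop("pedigree needs columns ", paste(need, collapse = ", "))
  for (col in c("father", "mother")) df[[col]][is.na(df[[col]])] <- ""
  if (anyDuplicated(df$id)) stop("duplicate individual id in pedigree")
  for (col in c("father", "mother")) {
    ref <- df[[col]][nzchar(df[[col]])]
    if (any(!ref %in% df$id))
      stop("parent id not in pedigree: ", ref[!ref %in% df$id][1])
  }
  sex_of <- function(ids) df$sex[match(ids, df$id)]
  f <- df$father[nzchar(df$father)]
  if (any(sex_of(f) == "F")) stop("a father is recorded as female")
  m <- df$mother[nzchar(df$mother)]
  if (any(sex_of(m) == "M")) stop("a mother is recorded as male")
  if (any(!df$status %in% c("carrier", "non_carrier", "unknown")))
    stop("status must be carrier, non_carrier or unknown")
  # acyclicity: every ancestor walk must terminate
  for (id in df$id) {
    seen <- character(0); frontier <- id
    while (length(frontier)) {
      if (any(frontier %in% seen)) stop("cyclic parent links at ", id)
      seen <- c(seen, frontier)
      rows <- match(frontier, df$id)
      frontier <- c(df$father[rows], df$mother[rows])
      frontier <- unique(frontier[nzchar(frontier)])
    }
  }
  class(df) <- c("pedigree", "data.frame")
  df
}

ancestors_of <- function(p, id) {
  out <- character(0); frontier <- id
  while (length(frontier)) {
    rows <- match(frontier, p$id)
    frontier <- unique(c(p$father[rows], p$mother[rows]))
    frontier <- frontier[nzchar(frontier)]
    frontier <- setdiff(frontier, out)
    out <- c(out, frontier)
  }
  out
}

#' Check Mendelian segregation of a dominant insertion allele
#'
#' A nuclear insertion segregates as an autosomal dominant marker: every
#' carrier must have a carrier parent (unless a founder). Conflicts are
#' reported for carriers both of whose parents are present with
#' `non_carrier` status; `unknown` parents never conflict
#' (conservative). Obligate carriers are unknown-status individuals
#' lying on a carrier-to-carrier descent path. Transmission tallies
#' count typed children of carrier parents.
#'
#' @param p a [pedigree()].
#' @return List of class `segregation_report`: `consistent`,
#'   `conflicts` (data frame id/father/mother), `obligate_carriers`
#'   (character), `transmissions` (list `transmitted`, `opportunities`).
#' @export
check_segregation <- function(p) {
  stopifnot(inherits(p, "pedigree"))
  status <- stats::setNames(p$status, p$id)
  carriers <- p$id[p$status == "carrier"]

  conflict_rows <- p[p$status == "carrier" &
                     nzchar(p$father) & nzchar(p$mother) &
                     status[p$father] == "non_carrier" &
                     status[p$mother] == "non_carrier",
                     c("id", "father", "mother"), drop = FALSE]
  rownames(conflict_rows) <- NULL

  anc <- lapply(stats::setNames(p$id, p$id), function(id) ancestors_of(p, id))
  obligate <- p$id[vapply(p$id, function(u) {
    if (status[u] != "unknown") return(FALSE)
    has_carrier_anc <- any(carriers %in% anc[[u]])
    has_carrier_desc_through <- any(vapply(carriers, function(d) {
      u %in% anc[[d]] && any(carriers %in% anc[[u]])
    }, TRUE))
    has_carrier_anc && has_carrier_desc_through
  }, TRUE)]

  typed_child <- p$status != "unknown"
  transmitted <- 0L; opportunities <- 0L
  for (i in seq_len(nrow(p))) {
    if (!typed_child[i]) next
    for (par in c(p$father[i], p$mother[i])) {
      if (nzchar(par) && status[par] == "carrier") {
        opportunities <- opportunities + 1L
        if (p$status[i] == "carrier") transmitted <- transmitted + 1L
      }
    }
  }

  structure(list(consistent = nrow(conflict_rows) == 0,
                 conflicts = conflict_rows,
                 obligate_carriers = obligate,
                 transmissions = list(transmitted = transmitted,
                                      opportunities = opportunities)),
            class = "segregation_report")
}

#' @export
print.segregation_report <- function(x, ...) {
  cat(sprintf("segregation %s: %d conflict(s); %d/%d carrier transmissions\n",
              if (x$consistent) "consistent" else "INCONSISTENT",
              nrow(x$conflicts), x$transmissions$transmitted,
              x$transmissions$opportunities))
  if (nrow(x$conflicts)) print(x$conflicts, row.names = FALSE)
  if (length(x$obligate_carriers))
    cat("obligate carriers:", paste(x$obligate_carriers, collapse = ", "), "\n")
  invisible(x)
}

#' Check strict maternal inheritance of the true mtDNA haplotype
#'
#' @param p a [pedigree()].
#' @param true_mitotypes named list of unambiguous [mitotype()]s, one
#'   per typed individual.
#' @return Data frame of violations (`id`, `mother`), one row per
#'   individual whose mitotype differs from their mother's. Individuals
#'   whose mother is absent or untyped are skipped.
#' @export
check_matriline <- function(p, true_mitotypes) {
  stopifnot(inherits(p, "pedigree"))
  bad_amb <- vapply(true_mitotypes, function(m) !is_unambiguous(m), TRUE)
  if (any(bad_amb))
    stop("mitotype for ", names(true_mitotypes)[bad_amb][1],
         " contains mixed-base calls")
  rows <- lapply(seq_len(nrow(p)), function(i) {
    id <- p$id[i]; mo <- p$mother[i]
    if (!nzchar(mo)) return(NULL)
    if (is.null(true_mitotypes[[id]]) || is.null(true_mitotypes[[mo]]))
      return(NULL)
    if (!mitotype_equal(true_mitotypes[[id]], true_mitotypes[[mo]]))
      data.frame(id = id, mother = mo, stringsAsFactors = FALSE)
    else NULL
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(id = character(), mother = character(),
                                      stringsAsFactors = FALSE)
  out
}
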