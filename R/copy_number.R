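# Quantification targets, ddPCR Poisson estimation, copies-per-NUMT and
# insert-size arithmetic, and the template-topology amplification test.

#' Registry of the study's quantification targets
#'
#' The ddPCR/qPCR amplification targets used to quantify mtDNA-like
#' sequence against nuclear references: four mtDNA-like amplicons (ND1,
#' KAV, BATZ, AND), a single-copy autosomal reference (ND14, GRCh38
#' chr14), and two multi-copy autosomal targets (RNU2, AluYb8) usable
#' for relative quantification only. Lengths of chrM targets are
#' inclusive circular-interval lengths.
#'
#' @return Data frame with columns `name`, `chromosome`, `start`, `end`,
#'   `length`, `copy_class`.
#' @examples
#' quant_targets()
#' @export
quant_targets <- function() {
  df <- data.frame(
    name       = c("ND1", "KAV", "BATZ", "AND", "ND14", "RNU2", "AluYb8"),
    chromosome = c("chrM", "chrM", "chrM", "chrM", "chr14", "autosomal",
                   "autosomal"),
    start      = c(3485L, 13288L, 8446L, 8294L, 94841905L, NA, NA),
    end        = c(3553L, 13392L, 8524L, 8436L, 94842013L, NA, NA),
    copy_class = c("mt_like", "mt_like", "mt_like", "mt_like",
                   "single_copy_autosomal", "multi_copy_autosomal",
                   "multi_copy_autosomal"),
    stringsAsFactors = FALSE)
  df$length <- ifelse(
    is.na(df$start), NA_integer_,
    ifelse(df$chromosome == "chrM",
           vapply(seq_len(nrow(df)), function(i) {
             if (is.na(df$start[i]) || df$chromosome[i] != "chrM") NA_integer_
             else circular_length(circular_interval(df$start[i], df$end[i]))
           }, 1L),
           df$end - df$start + 1L))
  df
}

#' Poisson mean copies per droplet from a digital PCR partition count
#'
#' Digital PCR partitions the template across ~20,000 droplets; with
#' `p` the positive-droplet fraction, the mean template copies per
#' droplet is the Poisson estimator `lambda = -ln(1 - p)`.
#'
#' @param n_positive positive droplet count.
#' @param n_droplets accepted droplet count (> 0).
#' @return `lambda`, mean copies per droplet (>= 0).
#' @examples
#' ddpcr_lambda(10000, 20000)  # log(2)
#' @export
ddpcr_lambda <- function(n_positive, n_droplets) {
  if (n_droplets <= 0) stop("n_droplets must be positive")
  if (n_positive < 0 || n_positive > n_droplets)
    stop("n_positive must lie in 0..n_droplets")
  if (n_positive == n_droplets)
    stop("all droplets positive: assay saturated, dilute and re-run")
  -log(1 - n_positive / n_droplets)
}

#' Template concentration from a droplet assay
#'
#' @param n_positive,n_droplets droplet counts (see [ddpcr_lambda()]).
#' @param droplet_volume_nl droplet volume in nanolitres (default 0.85).
#' @return Copies per nanolitre. Note that copies-per-NUMT estimation
#'   uses target ratios, in which the droplet volume cancels.
#' @export
ddpcr_concentration <- function(n_positive, n_droplets,
                                droplet_volume_nl = 0.85) {
  if (droplet_volume_nl <= 0) stop("droplet volume must be positive")
  ddpcr_lambda(n_positive, n_droplets) / droplet_volume_nl
}

#' Copies per NUMT from an mtDNA-like:single-copy-autosomal ratio
#'
#' A heterozygous insertion allele sits on one of `ploidy` homologues
#' while the single-copy autosomal reference counts all of them, so the
#' apparent mtDNA-like:autosomal ratio is multiplied by the ploidy.
#'
#' @param ratio_mt_to_autosomal apparent concentration ratio (>= 0).
#' @param ploidy reference copies per cell (default 2, diploid).
#' @return Estimated mitogenome copies per insertion allele.
#' @export
copies_per_numt <- function(ratio_mt_to_autosomal, ploidy = 2L) {
  if (any(ratio_mt_to_autosomal < 0)) stop("ratio must be >= 0")
  if (ploidy < 1) stop("ploidy must be >= 1")
  ratio_mt_to_autosomal * ploidy
}

#' Aggregate replicate ratios into a copy-number estimate
#'
#' Per-replicate copies are computed first (ratio times ploidy), then
#' summarized as their mean and sample standard deviation (denominator
#' n-1) with the replicate count, the reporting shape used for
#' mean +/- SD (n = ...) copy estimates.
#'
#' @param replicate_ratios numeric vector of apparent
#'   mtDNA-like:single-copy-autosomal ratios, one per replicate.
#' @param ploidy reference copies per cell (default 2).
#' @param target_names optional names per replicate for the per-target
#'   breakdown.
#' @return List of class `copy_estimate`: `copies_per_numt` (mean),
#'   `sd`, `n`, `per_target` (mean ratio per target name when given).
#' @export
aggregate_copies <- function(replicate_ratios, ploidy = 2L,
                             target_names = NULL) {
  if (length(replicate_ratios) < 1) stop("need at least one replicate")
  copies <- copies_per_numt(replicate_ratios, ploidy)
  sd <- if (length(copies) == 1) {
    warning("single replicate: standard deviation undefined, reported as NA")
    NA_real_
  } else stats::sd(copies)
  per_target <- if (!is.null(target_names))
    tapply(replicate_ratios, target_names, mean) else NULL
  structure(list(copies_per_numt = mean(copies), sd = sd,
                 n = length(copies), ploidy = ploidy,
                 per_target = per_target),
            class = "copy_estimate")
}

#' @export
print.copy_estimate <- function(x, ...) {
  cat(sprintf("%.2f +/- %s mitogenome copies per NUMT (n = %d)\n",
              x$copies_per_numt,
              if (is.na(x$sd)) "NA" else sprintf("%.2f", x$sd), x$n))
  invisible(x)
}

#' Nuclear insert size implied by a mitogenome copy number
#'
#' @param copies mitogenome copies per insertion (>= 0).
#' @param unit_length_bp repeat-unit length in bp (default 16569, one
#'   full mitogenome).
#' @return Insert size in bp.
#' @examples
#' insert_size(45)  # 745,605 bp, about 0.75 Mbp
#' @export
insert_size <- function(copies, unit_length_bp = 16569L) {
  if (any(copies < 0)) stop("copies must be >= 0")
  copies * unit_length_bp
}

#' Can a template topology support an amplicon?
#'
#' Long-range PCR across the mtDNA origin discriminates template
#' topologies: a circular genome supports any amplicon; a single
#' linearized unit spanning one contiguous run of mtDNA positions
#' supports an amplicon only if the amplicon occurs as a contiguous
#' sub-run (an origin-wrapping amplicon is never contained in a single
#' 1..16569 run); a tandem repeat of two or more full units realizes
#' every wrap across its unit junctions.
#'
#' @param template list describing the template: `list(type =
#'   "circular")`, `list(type = "linear_single_unit", span =
#'   circular_interval(...))`, or `list(type = "tandem_repeat", n = k)`
#'   with `k >= 2`.
#' @param amplicon a [circular_interval()] on chrM coordinates.
#' @return `TRUE` if the template can yield the amplicon.
#' @examples
#' long_range <- circular_interval(10653, 2688)  # wraps the origin
#' template_supports(list(type = "circular"), long_range)
#' template_supports(list(type = "linear_single_unit",
#'                        span = circular_interval(1, 16569)), long_range)
#' template_supports(list(type = "tandem_repeat", n = 2), long_range)
#' @export
template_supports <- function(template, amplicon) {
  stopifnot(inherits(amplicon, "circular_interval"))
  switch(template$type,
    circular = TRUE,
    tandem_repeat = {
      if (is.null(template$n) || template$n < 2)
        stop("tandem_repeat template needs n >= 2 units")
      TRUE
    },
    linear_single_unit = {
      span <- template$span
      stopifnot(inherits(span, "circular_interval"))
      run <- circular_positions(span)
      amp <- circular_positions(amplicon)
      if (length(amp) > length(run)) return(FALSE)
      starts <- which(run == amp[1])
      any(vapply(starts, function(s) {
        s + length(amp) - 1L <= length(run) &&
          identical(run[s:(s + length(amp) - 1L)], amp)
      }, TRUE))
    },
    stop("unknown template type: ", template$type))
}
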