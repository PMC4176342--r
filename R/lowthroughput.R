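#' Relative nucleosome occupancy from scanning qPCR
#'
#' Per replicate, occupancy is the mononucleosomal quantity divided by the
#' undigested input quantity (so the input itself scores 1 by
#' construction); per target and amplicon position the mean and SEM
#' (`sd/sqrt(n)`) over replicates are reported. Quantities are expected on a
#' linear abundance scale (post-Ct conversion); efficiency calibration is
#' upstream of this package.
#'
#' @param measurements Tibble with columns `target`, `replicate`,
#'   `mono_quantity`, `input_quantity`, and optionally `position` and
#'   `strain`.
#' @return Tibble with one row per target (and position): `mean_occupancy`,
#'   `sem` (`NA` when n < 2), `n`.
#' @examples
#' d <- tibble::tibble(target = "ctt1", replicate = 1:3,
#'                     mono_quantity = c(0.8, 1.0, 1.2), input_quantity = 1)
#' relative_occupancy(d)
#' @export
relative_occupancy <- function(measurements) {
  if (any(measurements$input_quantity <= 0)) {
    abort("input_quantity must be > 0 for every replicate")
  }
  grp <- intersect(c("target", "position", "strain"), names(measurements))
  measurements |>
    mutate(occupancy = .data$mono_quantity / .data$input_quantity) |>
    group_by(across(all_of(grp))) |>
    summarise(
      mean_occupancy = mean(.data$occupancy),
      sem = if (dplyr::n() >= 2) sd(.data$occupancy) / sqrt(dplyr::n()) else NA_real_,
      n = dplyr::n(),
      .groups = "drop"
    )
}

# Delta-method SEM of a ratio: relative variances add in quadrature.
ratio_sem <- function(ratio, mean_num, sem_num, mean_den, sem_den) {
  ratio * sqrt((sem_num / mean_num)^2 + (sem_den / mean_den)^2)
}

#' Occupancy ratio between two strains
#'
#' Per-target ratio of mean occupancies (test over reference, so the
#' reference strain scores 1), with SEM propagated by the delta method. A
#' control target's ratio (e.g. a gene whose occupancy should not depend on
#' the barrier factor) can be reported alongside as a sanity value, and
#' optionally used to normalize the other ratios.
#'
#' @param occ_test,occ_ref Occupancy tables from [relative_occupancy()] for
#'   the test and reference strains.
#' @param control_target Optional control target name.
#' @param normalize_to_control Divide every ratio by the control's ratio?
#'   (Off by default; the control is then display-only.)
#' @return Tibble with columns `target` (and `position`), `ratio`, `sem`,
#'   `is_control`.
#' @export
strain_ratio <- function(occ_test, occ_ref, control_target = NULL,
                         normalize_to_control = FALSE) {
  by <- intersect(c("target", "position"), intersect(names(occ_test), names(occ_ref)))
  j <- inner_join(occ_test, occ_ref, by = by, suffix = c("_test", "_ref"))
  if (nrow(j) == 0) abort("test and reference share no targets")
  if (any(j$mean_occupancy_ref <= 0)) {
    abort("reference mean occupancy must be > 0")
  }
  out <- j |>
    mutate(
      ratio = .data$mean_occupancy_test / .data$mean_occupancy_ref,
      sem = ratio_sem(.data$ratio, .data$mean_occupancy_test, .data$sem_test,
                      .data$mean_occupancy_ref, .data$sem_ref),
      is_control = if (is.null(control_target)) FALSE else .data$target == control_target
    ) |>
    select(all_of(by), "ratio", "sem", "is_control")
  if (normalize_to_control) {
    if (is.null(control_target) || !any(out$is_control)) {
      abort("normalize_to_control requires a control_target present in the data")
    }
    ctrl <- out$ratio[out$is_control][1]
    out$ratio <- out$ratio / ctrl
  }
  out
}

#' Strand-specific transcript fold changes
#'
#' Per gene and strand (sense/antisense), the fold change of the mean
#' quantity in each strain relative to the reference strain (reference = 1),
#' with SEM propagated by the delta method (`method = "ratio_of_means"`,
#' the default) or computed across per-replicate ratios paired by replicate
#' index (`method = "mean_of_ratios"`).
#'
#' @param measurements Tibble with columns `gene_id`, `strand_sense`,
#'   `quantity`, `replicate`, `strain`.
#' @param reference_strain Name of the reference strain.
#' @param method Fold-change estimator (see above).
#' @return Tibble with columns `gene_id`, `strand_sense`, `strain`, `fold`,
#'   `sem`, `n`.
#' @export
transcript_fold_change <- function(measurements, reference_strain,
                                   method = c("ratio_of_means", "mean_of_ratios")) {
  method <- match.arg(method)
  if (!reference_strain %in% measurements$strain) {
    abort(sprintf("reference strain '%s' absent from the data", reference_strain))
  }
  ref <- filter(measurements, .data$strain == reference_strain)
  test <- filter(measurements, .data$strain != reference_strain)
  missing <- anti_join(distinct(test, .data$gene_id, .data$strand_sense),
                       distinct(ref, .data$gene_id, .data$strand_sense),
                       by = c("gene_id", "strand_sense"))
  if (nrow(missing) > 0) {
    abort(sprintf("gene(s) missing from reference strain: %s",
                  paste(unique(missing$gene_id), collapse = ", ")))
  }
  summarise_strain <- function(d) {
    d |>
      group_by(.data$gene_id, .data$strand_sense, .data$strain) |>
      summarise(m = mean(.data$quantity),
                s = if (dplyr::n() >= 2) sd(.data$quantity) / sqrt(dplyr::n()) else NA_real_,
                n = dplyr::n(), .groups = "drop")
  }
  refs <- summarise_strain(ref) |>
    select("gene_id", "strand_sense", m_ref = "m", s_ref = "s")
  if (method == "ratio_of_means") {
    summarise_strain(measurements) |>
      inner_join(refs, by = c("gene_id", "strand_sense")) |>
      mutate(fold = .data$m / .data$m_ref,
             sem = ratio_sem(.data$fold, .data$m, .data$s,
                             .data$m_ref, .data$s_ref)) |>
      select("gene_id", "strand_sense", "strain", "fold", "sem", "n")
  } else {
    measurements |>
      inner_join(select(ref, "gene_id", "strand_sense", "replicate",
                        q_ref = "quantity"),
                 by = c("gene_id", "strand_sense", "replicate")) |>
      mutate(r = .data$quantity / .data$q_ref) |>
      group_by(.data$gene_id, .data$strand_sense, .data$strain) |>
      summarise(fold = mean(.data$r),
                sem = if (dplyr::n() >= 2) sd(.data$r) / sqrt(dplyr::n()) else NA_real_,
                n = dplyr::n(), .groups = "drop")
  }
}
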