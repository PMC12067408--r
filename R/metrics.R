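#' Dice similarity coefficient
#'
#' `Dice = 2 |A intersect B| / (|A| + |B|)` for the binary masks of `label`
#' in two volumes on the same grid; 1 indicates perfect overlap. When both
#' masks are empty the coefficient is defined as 1 (perfect-agreement
#' reading of the 0/0 case) and flagged via the `"empty"` attribute.
#'
#' @param a,b [label_volume()] objects on the same grid.
#' @param label Integer label (0..4) or one of `names(heart_labels)`.
#' @return Dice value in `[0, 1]` (attribute `empty` = TRUE when 0/0).
#' @export
dice <- function(a, b, label) {
  if (!same_grid(a, b)) stop("Dice requires identical grids")
  if (is.character(label)) label <- heart_labels[[label]]
  ma <- a$values == label
  mb <- b$values == label
  na <- sum(ma); nb <- sum(mb)
  if (na + nb == 0) return(structure(1, empty = TRUE))
  2 * sum(ma & mb) / (na + nb)
}

#' Mean foreground Dice
#'
#' Convenience average of the four foreground labels (LV cavity, LV wall,
#' RV cavity, RV wall).
#'
#' @inheritParams dice
#' @return Mean Dice over labels 1-4.
#' @export
mean_dice <- function(a, b) {
  mean(vapply(1:4, function(l) as.numeric(dice(a, b, l)), 0))
}

#' Slice-by-slice Dice
#'
#' Dice per z-slice for one label. Slices empty in both volumes are
#' omitted; their count is reported in the `n_empty` attribute.
#'
#' @inheritParams dice
#' @return Tibble with `slice` and `dice`; attribute `n_empty`.
#' @export
slicewise_dice <- function(a, b, label) {
  if (!same_grid(a, b)) stop("Dice requires identical grids")
  if (is.character(label)) label <- heart_labels[[label]]
  nz <- dim(a$values)[3]
  rows <- lapply(seq_len(nz), function(k) {
    ma <- a$values[, , k] == label
    mb <- b$values[, , k] == label
    if (sum(ma) + sum(mb) == 0) return(NULL)
    tibble::tibble(slice = k, dice = 2 * sum(ma & mb) / (sum(ma) + sum(mb)))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "n_empty") <- nz - nrow(out)
  out
}

#' Cardiac indices from ED/ES segmentations
#'
#' Volumes are voxel counts times voxel volume (uL). Per ventricle:
#' `SV = EDV - ESV`, `EF = SV/EDV * 100`, `CO = heart_rate * SV / 1000`
#' (formula units; note bpm x uL / 1000 is mL/min). Myocardial mass uses
#' the specific density 1.05 g/mL (so mg = 1.05 x uL of ED wall volume);
#' LV mass includes the septum by the labeling convention. Body surface
#' area follows Meeh's allometric formula `BSA = k W^(2/3) / 10000` with
#' k = 10 and W in grams, giving m^2; `_i` columns are BSA-indexed.
#'
#' @param lab_ed,lab_es ED and ES [label_volume()] objects.
#' @param heart_rate Heart rate (bpm).
#' @param body_weight Body weight (g).
#' @return Tibble: one row per ventricle with EDV/ESV/SV/EF/CO, mass, BSA
#'   and BSA-indexed variants.
#' @export
cardiac_indices <- function(lab_ed, lab_es, heart_rate, body_weight) {
  stopifnot(heart_rate > 0, body_weight > 0)
  vv_ed <- voxel_volume_ul(lab_ed)
  vv_es <- voxel_volume_ul(lab_es)
  bsa <- 10 * body_weight^(2 / 3) / 10000
  row <- function(vent, cav, wall) {
    edv <- sum(lab_ed$values == cav) * vv_ed
    esv <- sum(lab_es$values == cav) * vv_es
    if (edv <= 0) stop(sprintf("EDV is zero for %s: EF undefined", vent))
    sv <- edv - esv
    mass <- 1.05 * sum(lab_ed$values == wall) * vv_ed
    tibble::tibble(
      ventricle = vent, edv_ul = edv, esv_ul = esv, sv_ul = sv,
      ef_pct = sv / edv * 100, co = heart_rate * sv / 1000,
      mass_mg = mass, bsa_m2 = bsa,
      edv_i = edv / bsa, esv_i = esv / bsa, sv_i = sv / bsa,
      co_i = heart_rate * sv / 1000 / bsa, mass_i = mass / bsa)
  }
  dplyr::bind_rows(row("LV", heart_labels[["lv_cavity"]],
                       heart_labels[["lv_wall"]]),
                   row("RV", heart_labels[["rv_cavity"]],
                       heart_labels[["rv_wall"]]))
}

#' Bland-Altman method agreement
#'
#' Bias (mean of auto - manual), SD of the differences, limits of agreement
#' `bias +/- 1.96 SD`, and the Pearson correlation of the paired values.
#'
#' @param auto,manual Paired numeric vectors (n >= 3).
#' @return Tibble with `bias`, `sd_diff`, `loa_lower`, `loa_upper`, `r`,
#'   `n`.
#' @export
agreement <- function(auto, manual) {
  stopifnot(length(auto) == length(manual), length(auto) >= 3)
  d <- auto - manual
  bias <- mean(d)
  s <- sd(d)
  r <- if (sd(auto) == 0 || sd(manual) == 0) {
    if (all(d == d[1])) 1 else NA_real_
  } else cor(auto, manual)
  tibble::tibble(bias = bias, sd_diff = s,
                 loa_lower = bias - 1.96 * s, loa_upper = bias + 1.96 * s,
                 r = r, n = length(d))
}

#' Per-subject segmentation evaluation table
#'
#' Tidy per-label Dice rows for one subject, suitable for binding across a
#' cohort.
#'
#' @param auto,manual Label volumes to compare.
#' @param subject Subject id recorded in the rows.
#' @return Tibble: subject, label name, dice.
#' @export
evaluate_labels <- function(auto, manual, subject = "subject") {
  nm <- names(heart_labels)[-1]
  tibble::tibble(
    subject = subject, label = nm,
    dice = unname(vapply(nm, function(l) as.numeric(dice(auto, manual, l)),
                         0)))
}
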