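#' Cell number from a Neubauer chamber count
#'
#' `cells = (count / squares) * chamber_factor * volume_mL`. The standard
#' hemocytometer convention is `chamber_factor = 1e4` cells/mL per count
#' in one large square.
#'
#' @param count cells counted.
#' @param squares number of large squares counted (>= 1).
#' @param volume_ml volume of the counted cell suspension, mL.
#' @param chamber_factor cells/mL per count per square.
#' @return cell number (vectorized).
#' @export
cells_from_count <- function(count, squares, volume_ml,
                             chamber_factor = 1e4) {
  if (any(squares < 1, na.rm = TRUE))
    stop("squares must be >= 1", call. = FALSE)
  stopifnot(all(count >= 0, na.rm = TRUE), all(volume_ml > 0, na.rm = TRUE))
  (count / squares) * chamber_factor * volume_ml
}

#' Exponential growth rate from two cell counts
#'
#' `r = ln(n1 / n0) / t`, the rate of the exponential through the
#' before-seeding and after-conditioning counts. Negative rates
#' (shrinking cultures) are allowed.
#'
#' @param n0,n1 cell numbers (> 0) at the start and end of the interval.
#' @param t interval length in days (> 0).
#' @return growth rate per day (vectorized).
#' @export
fit_exponential <- function(n0, n1, t) {
  if (any(n0 <= 0 | n1 <= 0, na.rm = TRUE))
    stop("cell counts must be positive (log undefined)", call. = FALSE)
  if (any(t <= 0, na.rm = TRUE))
    stop("interval must be positive", call. = FALSE)
  log(n1 / n0) / t
}

#' Area under the exponential growth curve
#'
#' `AUC = n0 * (exp(r t) - 1) / r` cell-days, with the continuous limit
#' `n0 * t` at `r = 0`. Uses `expm1()` so tiny rates suffer no
#' cancellation: the value is continuous through `r = 0`.
#'
#' @param n0 starting cell number (> 0).
#' @param r growth rate per day.
#' @param t interval in days (> 0).
#' @return cell-days (always positive; vectorized).
#' @export
growth_auc <- function(n0, r, t) {
  stopifnot(all(n0 > 0, na.rm = TRUE), all(t > 0, na.rm = TRUE))
  ifelse(r == 0, n0 * t, n0 * expm1(r * t) / r)
}

#' Net secreted cytokine amount
#'
#' Subtracts the medium-only control concentration and converts to an
#' absolute amount over the conditioned-medium volume:
#' `net = (sample - control) * volume` pg. Negative values (apparent
#' consumption) are kept, not floored, so paired tests stay unbiased;
#' callers can flag them.
#'
#' @param sample_conc,control_conc concentrations in pg/mL (>= 0).
#' @param medium_volume_ml conditioned-medium volume in mL.
#' @return net amount in pg (vectorized).
#' @export
net_cytokine <- function(sample_conc, control_conc, medium_volume_ml) {
  stopifnot(all(sample_conc >= 0, na.rm = TRUE),
            all(control_conc >= 0, na.rm = TRUE))
  (sample_conc - control_conc) * medium_volume_ml
}

# Columns of the growth/cytokine schema that are not cytokine readouts.
SCHEMA_COLS <- c("Culture", "Epoch", "Dose.IFNg", "Dose.TNFa",
                 "Count.B", "Squares.B", "Volume.B", "Days",
                 "Count.A", "Squares.A", "Volume.A", "Medium")

#' Growth-normalized secretion rates
#'
#' For each culture row: converts both Neubauer counts to cell numbers,
#' fits the exponential rate over the `Days` interval, integrates it to
#' the growth AUC, subtracts the mean medium-only control concentration
#' per cytokine, and divides the net amount by the AUC. The result is a
#' per-cell-day secretion rate (pg / cell-day) that is comparable across
#' cultures growing at different speeds.
#'
#' @param tbl table in the [simulate_growth_cytokines()] schema; rows
#'   with `Epoch == "control"` are the medium-only controls.
#' @param chamber_factor Neubauer conversion factor.
#' @param cytokines cytokine column names (default: every non-schema
#'   column).
#' @return tidy tibble: `culture_id`, `epoch`, `dose_ifng`, `dose_tnfa`,
#'   `cytokine`, `net_pg`, `auc_cell_days`, `rate_pg_per_cell_day`,
#'   `negative_net` flag.
#' @export
normalize_secretome <- function(tbl, chamber_factor = 1e4,
                                cytokines = NULL) {
  if (is.null(cytokines)) cytokines <- setdiff(names(tbl), SCHEMA_COLS)
  if (!length(cytokines)) stop("no cytokine columns found", call. = FALSE)
  ctrl <- tbl[tbl$Epoch == "control", , drop = FALSE]
  if (nrow(ctrl) == 0L)
    stop("no medium-only control rows (Epoch == 'control')", call. = FALSE)
  control_conc <- vapply(cytokines, function(cy) mean(ctrl[[cy]]), numeric(1))
  cult <- tbl[tbl$Epoch != "control", , drop = FALSE]
  n0 <- cells_from_count(cult$Count.B, cult$Squares.B, cult$Volume.B,
                         chamber_factor)
  n1 <- cells_from_count(cult$Count.A, cult$Squares.A, cult$Volume.A,
                         chamber_factor)
  r <- fit_exponential(n0, n1, cult$Days)
  auc <- growth_auc(n0, r, cult$Days)
  out <- lapply(seq_along(cytokines), function(j) {
    cy <- cytokines[[j]]
    net <- net_cytokine(cult[[cy]], control_conc[[j]], cult$Medium)
    tibble::tibble(culture_id = cult$Culture, epoch = cult$Epoch,
                   dose_ifng = cult$Dose.IFNg, dose_tnfa = cult$Dose.TNFa,
                   cytokine = cy, net_pg = net, auc_cell_days = auc,
                   rate_pg_per_cell_day = net / auc,
                   negative_net = net < 0)
  })
  dplyr::bind_rows(out)
}

#' Paired early-versus-late Wilcoxon signed-rank test
#'
#' The pairing unit is the combination of produced cytokine and
#' activation dose: for each (cytokine, dose) pair, the mean normalized
#' rate over replicate cultures in the early epoch is paired with its
#' late counterpart. Two-sided signed-rank test on the paired
#' differences; zero differences are dropped (the common signed-rank
#' convention, exposed via `zero_method`); the exact null distribution is
#' used for up to 25 untied non-zero pairs, the normal approximation with
#' continuity correction otherwise.
#'
#' @param normalized tibble from [normalize_secretome()].
#' @param value column to compare (default the normalized rate).
#' @param zero_method `"drop"` (default) or `"keep"` (zeros retained and
#'   handled by the normal approximation).
#' @return list: `statistic` (V), `p_value`, `n_pairs` (non-zero pairs
#'   used), `degenerate` (TRUE when all pairs are tied early = late).
#' @export
paired_wilcoxon_early_late <- function(normalized,
                                       value = "rate_pg_per_cell_day",
                                       zero_method = c("drop", "keep")) {
  zero_method <- match.arg(zero_method)
  agg <- dplyr::summarise(
    dplyr::group_by(normalized, .data$cytokine, .data$dose_ifng,
                    .data$dose_tnfa, .data$epoch),
    value = mean(.data[[value]]), .groups = "drop")
  wide <- merge(agg[agg$epoch == "early", ], agg[agg$epoch == "late", ],
                by = c("cytokine", "dose_ifng", "dose_tnfa"),
                suffixes = c("_early", "_late"))
  if (nrow(wide) == 0L)
    stop("no (cytokine, dose) pair has both an early and a late value",
         call. = FALSE)
  d <- wide$value_late - wide$value_early
  if (all(d == 0))
    return(list(statistic = 0, p_value = 1, n_pairs = 0L,
                degenerate = TRUE))
  if (sum(d != 0) < 2L)
    stop("fewer than 2 non-zero pairs: insufficient data", call. = FALSE)
  if (zero_method == "drop") {
    dd <- d[d != 0]
    exact <- length(dd) <= 25L && !any(duplicated(abs(dd)))
    wt <- suppressWarnings(stats::wilcox.test(
      dd, exact = exact, correct = TRUE))
    list(statistic = unname(wt$statistic), p_value = wt$p.value,
         n_pairs = length(dd), degenerate = FALSE)
  } else {
    # Pratt: rank |d| with zeros included, discard the zeros' ranks from
    # the statistic; normal approximation with continuity correction.
    n <- length(d)
    z <- sum(d == 0)
    rk <- rank(abs(d))
    v <- sum(rk[d > 0])
    e <- (n * (n + 1) / 2 - z * (z + 1) / 2) / 2
    va <- (n * (n + 1) * (2 * n + 1) - z * (z + 1) * (2 * z + 1)) / 24
    p <- 2 * stats::pnorm((abs(v - e) - 0.5) / sqrt(va), lower.tail = FALSE)
    list(statistic = v, p_value = min(1, p), n_pairs = n - z,
         degenerate = FALSE)
  }
}
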