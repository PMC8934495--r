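#' Peak force of a muscle group
#'
#' Group force over a motion, defined as the sum over the group's elements
#' of each element's peak force in time (sum-of-element-peaks). This matches
#' the peak-activation definition used for the summary tables; the
#' alternative reducer (peak of the summed series, always <= the default) is
#' available via `reducer`.
#'
#' @param forces n_steps x n_elements matrix of element forces (N), with
#'   element names as column names.
#' @param groups named character vector mapping element name to group.
#' @param group group to summarise.
#' @param reducer `"sum_of_peaks"` (default) or `"peak_of_sum"`.
#' @return Peak group force (N).
#' @export
peak_group_force <- function(forces, groups, group,
                             reducer = c("sum_of_peaks", "peak_of_sum")) {
  reducer <- match.arg(reducer)
  idx <- names(groups)[groups == group]
  if (length(idx) == 0) stop("no elements in group '", group, "'")
  if (nrow(forces) == 0) stop("empty force series")
  sub <- forces[, idx, drop = FALSE]
  if (reducer == "sum_of_peaks") sum(apply(sub, 2, max)) else max(rowSums(sub))
}

#' Peak group activation
#'
#' The sum of the element peak forces of a group divided by the sum of the
#' maximal isometric forces of those elements: the average relative effort
#' of the group, in `[0, 1]` for forces within capacity. Reported rounded to
#' 2 decimals in tables.
#'
#' @param group_peak_forces element peak forces (N).
#' @param group_fmax_values matching maximal isometric forces (N).
#' @return Dimensionless activation.
#' @export
group_activation <- function(group_peak_forces, group_fmax_values) {
  s <- sum(group_fmax_values)
  if (s <= 0) stop("sum of maximal isometric forces must be positive")
  sum(group_peak_forces) / s
}

#' Percent change relative to the natural-shoulder value
#'
#' `round(100 * (model - ns) / ns)` with round-half-away-from-zero, the
#' rounding that reproduces every printed percent-change cell of the
#' packaged summary-table fixture.
#'
#' @param ns_value baseline (natural shoulder) value, > 0.
#' @param model_value value for the prosthesis model.
#' @return Signed integer percent.
#' @export
percent_change <- function(ns_value, model_value) {
  if (any(ns_value <= 0)) stop("baseline value must be positive")
  p <- 100 * (model_value - ns_value) / ns_value
  sign(p) * floor(abs(p) + 0.5)
}

#' Deltoid and rotator cuff totals
#'
#' Sums subgroup peak forces into the two headline aggregates: deltoid =
#' anterior + middle + posterior deltoid; rotator cuff = supraspinatus (0 if
#' absent, as in the prosthesis models) + infraspinatus + teres minor +
#' subscapularis.
#'
#' @param peaks data frame with columns `row` (group name) and `force_N` for
#'   one model and motion.
#' @return List with `deltoid_total` and `rotator_cuff_total` (N).
#' @export
aggregate_muscle_groups <- function(peaks) {
  get1 <- function(g, optional = FALSE) {
    v <- peaks$force_N[peaks$row == g]
    v <- v[!is.na(v)]
    if (length(v) == 0) {
      if (optional) return(0)
      stop("missing subgroup '", g, "'")
    }
    sum(v)
  }
  list(
    deltoid_total = get1("anterior_deltoid") + get1("middle_deltoid") +
      get1("posterior_deltoid"),
    rotator_cuff_total = get1("supraspinatus", optional = TRUE) +
      get1("infraspinatus") + get1("teres_minor") + get1("subscapularis"))
}

#' Peak table from solved motions
#'
#' Builds the summary-table-shaped data frame: one row per (model, motion,
#' muscle group) with the peak group force and activation, plus one JRF row
#' per (model, motion). Groups with no active elements (the supraspinatus in
#' the prosthesis models) are absent.
#'
#' @param solutions nested list `solutions[[variant]][[motion]]` of
#'   `shoulder_solution` objects (as produced by [run_pipeline()]).
#' @return A data frame with columns `model`, `motion`, `row`, `force_N`,
#'   `activation`, of class `c("peak_table", "data.frame")`.
#' @export
peak_table <- function(solutions) {
  out <- list()
  for (v in names(solutions)) for (mo in names(solutions[[v]])) {
    sol <- solutions[[v]][[mo]]
    for (g in unique(sol$groups)) {
      idx <- which(sol$groups == g & sol$active)
      if (length(idx) == 0) next
      pk <- apply(sol$forces[, idx, drop = FALSE], 2, max)
      out[[length(out) + 1L]] <- data.frame(
        model = v, motion = mo, row = g,
        force_N = sum(pk),
        activation = group_activation(pk, sol$f_max[idx]))
    }
    out[[length(out) + 1L]] <- data.frame(
      model = v, motion = mo, row = "JRF", force_N = max(sol$jrf),
      activation = NA_real_)
  }
  res <- do.call(rbind, out)
  class(res) <- c("peak_table", "data.frame")
  res
}

#' Percent changes relative to a baseline model
#'
#' @param peaks a peak table (from [peak_table()] or
#'   [load_table1_fixture()]).
#' @param baseline baseline model tag, default `"NS"`.
#' @return Data frame with `model`, `motion`, `row`,
#'   `percent_change_from_ns` for every non-baseline row present in the
#'   baseline.
#' @export
comparison_table <- function(peaks, baseline = "NS") {
  base <- peaks[peaks$model == baseline, ]
  rest <- peaks[peaks$model != baseline, ]
  out <- list()
  for (i in seq_len(nrow(rest))) {
    b <- base$force_N[base$motion == rest$motion[i] & base$row == rest$row[i]]
    if (length(b) != 1 || is.na(b) || b <= 0 || is.na(rest$force_N[i])) next
    out[[length(out) + 1L]] <- data.frame(
      model = rest$model[i], motion = rest$motion[i], row = rest$row[i],
      percent_change_from_ns = percent_change(b, rest$force_N[i]))
  }
  do.call(rbind, out)
}

# md5 of the packaged fixture; the fixture is part of the test oracle and
# must not drift silently
.table1_md5 <- "156272f5f4ec321835f544bf18ac10d8"

#' Load the packaged peak-force summary fixture
#'
#' Returns the packaged table of peak muscle forces, activations and joint
#' reaction forces for the three shoulder configurations over the four
#' motions (natural shoulder, reverse prosthesis, dual-bearing prosthesis),
#' together with the printed percent-change columns for cross-validation.
#' The file checksum is verified; a mismatch is an error. One
#' scaption JRF percent cell is typographically corrupted in the source and
#' carries `asserted = FALSE`.
#'
#' @return Data frame with columns `model`, `motion`, `row`, `force_N`,
#'   `activation`, `pct_change` (printed percent change vs NS, NA for NS
#'   rows), `asserted`; class `c("peak_table", "data.frame")`.
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_peaks.csv", package = "shouldersim")
  if (path == "" || !file.exists(path)) stop("packaged fixture not found")
  md5 <- unname(tools::md5sum(path))
  if (!identical(md5, .table1_md5)) {
    stop("fixture checksum mismatch: expected ", .table1_md5, ", got ", md5)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  df$asserted <- as.logical(df$asserted)
  class(df) <- c("peak_table", "data.frame")
  df
}

#' Headline aggregate comparisons
#'
#' Computes, from a peak table, the headline percent changes: total deltoid
#' and total rotator cuff peak force of the dual-bearing prosthesis relative
#' to the natural shoulder for each motion, and the peak JRF percent changes
#' of both prostheses relative to the natural shoulder.
#'
#' @param peaks a peak table covering NS and at least one prosthesis model.
#' @return Data frame with columns `quantity` (`"deltoid_total"`,
#'   `"rotator_cuff_total"` or `"JRF"`), `model`, `motion`, `value_N`,
#'   `ns_value_N`, `percent_change_from_ns`.
#' @export
headline_comparisons <- function(peaks) {
  motions <- unique(peaks$motion)
  out <- list()
  for (mo in motions) {
    ns <- aggregate_muscle_groups(peaks[peaks$model == "NS" &
                                          peaks$motion == mo, ])
    for (mdl in setdiff(unique(peaks$model), "NS")) {
      sub <- peaks[peaks$model == mdl & peaks$motion == mo, ]
      if (nrow(sub) == 0) next
      if (mdl == "DBSP") {
        agg <- aggregate_muscle_groups(sub)
        for (qn in c("deltoid_total", "rotator_cuff_total")) {
          out[[length(out) + 1L]] <- data.frame(
            quantity = qn, model = mdl, motion = mo,
            value_N = agg[[qn]], ns_value_N = ns[[qn]],
            percent_change_from_ns = percent_change(ns[[qn]], agg[[qn]]))
        }
      }
      jn <- peaks$force_N[peaks$model == "NS" & peaks$motion == mo &
                            peaks$row == "JRF"]
      jm <- sub$force_N[sub$row == "JRF"]
      if (length(jn) == 1 && length(jm) == 1) {
        out[[length(out) + 1L]] <- data.frame(
          quantity = "JRF", model = mdl, motion = mo,
          value_N = jm, ns_value_N = jn,
          percent_change_from_ns = percent_change(jn, jm))
      }
    }
  }
  do.call(rbind, out)
}
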