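#' Binned distribution of donations or aspirations
#'
#' Histogram with eleven bins over `[0, endowment]`: bin `n` (for
#' `n = 0, ..., 9`) counts values with `n/10 <= x/endowment < (n+1)/10`
#' (half-open intervals), and bin 10 holds the single value
#' `x == endowment`. Frequencies are normalized to sum to 1.
#'
#' @param values numeric vector of donations or aspirations in
#'   `[0, endowment]`.
#' @param endowment the pie size.
#' @return Named numeric vector of length 11 (names `"0"` to `"10"`).
#' @export
donation_histogram <- function(values, endowment = 1) {
  if (length(values) == 0L) stop("'values' must be non-empty", call. = FALSE)
  if (any(values < 0 | values > endowment))
    stop("'values' outside [0, endowment]", call. = FALSE)
  edges <- (0:10) * endowment / 10
  bin <- findInterval(values, edges)  # 1..11; endowment lands in 11
  counts <- tabulate(bin, nbins = 11L)
  stats::setNames(counts / length(values), as.character(0:10))
}

#' Mean donation
#'
#' Arithmetic mean of a donation vector; errors on empty input.
#'
#' @param values non-empty numeric vector.
#' @return The mean.
#' @export
mean_donation <- function(values) {
  if (length(values) == 0L) stop("'values' must be non-empty", call. = FALSE)
  mean(values)
}

#' Sample Gini coefficient
#'
#' The standard Gini coefficient: the mean absolute difference between all
#' (ordered) pairs, including self-pairs, divided by twice the mean,
#' `G = sum_ij |x_i - x_j| / (2 n^2 mean(x))`. Computed via the sorted-data
#' closed form. 0 for an all-equal distribution, approaches 1 when all mass
#' sits on one value. An all-zero vector has an undefined Gini; by convention
#' 0 is returned with a warning (no dispersion).
#'
#' @param values non-empty numeric vector of non-negative values.
#' @return Gini coefficient in `[0, 1]`.
#' @export
gini_coefficient <- function(values) {
  if (length(values) == 0L) stop("'values' must be non-empty", call. = FALSE)
  if (any(values < 0)) stop("'values' must be non-negative", call. = FALSE)
  n <- length(values)
  total <- sum(values)
  if (total == 0) {
    warning("Gini coefficient undefined for all-zero input; returning 0",
            call. = FALSE)
    return(0)
  }
  x <- sort(values)
  (2 * sum(seq_len(n) * x)) / (n * total) - (n + 1) / n
}

#' Equality index of a donation distribution
#'
#' One minus the sample Gini coefficient ([gini_coefficient()]): 1 for a
#' perfectly homogeneous (all-equal) distribution, smaller when donations are
#' more heterogeneous. This orientation quantifies the adherence to a common
#' giving norm: values near 1 mean almost no deviant donors. An all-zero
#' vector returns 1 (everyone identical) with a warning.
#'
#' @param values non-empty numeric vector of non-negative values.
#' @return Equality index `G` in `[0, 1]`.
#' @export
equality_index <- function(values) {
  1 - gini_coefficient(values)
}

#' Concentration (histogram Gini) of a donation distribution
#'
#' The Gini coefficient of the eleven bin frequencies of the 0.1-wide
#' histogram ([donation_histogram()]): a measure of how concentrated the
#' binned distribution is. It approaches its maximum of 10/11 when all mass
#' sits in a single bin -- a population unanimously following one giving
#' norm, with almost no deviant donors -- and 0 when every bin is equally
#' occupied. Unlike [equality_index()], which compares donation *values*
#' pairwise, this statistic quantifies the diversity of the *distribution*:
#' a population uniformly donating zero scores near 1 here (no diversity)
#' while its value-based equality index is dominated by the few positive
#' donors.
#'
#' @param values non-empty numeric vector of donations in `[0, endowment]`.
#' @param endowment the pie size.
#' @return Gini coefficient of the bin frequencies, in `[0, 10/11]`.
#' @export
histogram_gini <- function(values, endowment = 1) {
  gini_coefficient(donation_histogram(values, endowment))
}

#' Pool a parameter sweep into distributions and summary statistics
#'
#' Takes per-cell replication results (one cell = one `(l, h)` combination)
#' and produces: per-cell donation and aspiration histograms averaged over
#' replications with across-replication standard deviations, and pooled
#' statistics (mean donation, equality index, raw Gini) computed on the
#' concatenation of all final-state donation vectors over every cell and
#' replication.
#'
#' @param cells list of cells; each cell is a list with numeric `l`, `h` and
#'   `runs`, a list of `dg_run` objects sharing `endowment` and `n_agents`.
#' @return An object of class `dg_sweep`: list with
#'   \describe{
#'     \item{cell_table}{data frame with columns `l`, `h`, `quantity`
#'       (`"donation"`/`"aspiration"`), `bin` (0-10), `freq_mean`, `freq_sd`.}
#'     \item{pooled_donations, pooled_aspirations}{concatenated final-state
#'       vectors.}
#'     \item{mean_donation, histogram_gini, equality_index, gini}{pooled
#'       summary statistics of the donations: arithmetic mean, concentration
#'       of the binned distribution ([histogram_gini()], the `G` statistic
#'       used to summarise conditions), value-based equality index and raw
#'       sample Gini.}
#'     \item{n_runs, convergence_steps, n_converged}{replication metadata.}
#'     \item{endowment, n_agents}{shared condition constants.}
#'   }
#' @export
pool_sweep <- function(cells) {
  if (length(cells) == 0L) stop("'cells' must be non-empty", call. = FALSE)
  all_runs <- unlist(lapply(cells, `[[`, "runs"), recursive = FALSE)
  if (length(all_runs) == 0L) stop("no runs in 'cells'", call. = FALSE)
  phi <- unique(vapply(all_runs, function(r) r$params$endowment, numeric(1)))
  n_agents <- unique(vapply(all_runs, function(r) r$params$n_agents,
                            integer(1)))
  if (length(phi) != 1L || length(n_agents) != 1L)
    stop("all cells must share 'endowment' and 'n_agents'", call. = FALSE)

  cell_frame <- function(cell) {
    hd <- vapply(cell$runs,
                 function(r) donation_histogram(r$final_donations, phi),
                 numeric(11))
    ha <- vapply(cell$runs,
                 function(r) donation_histogram(r$final_aspirations, phi),
                 numeric(11))
    sd0 <- function(m) if (ncol(m) > 1L) apply(m, 1L, sd) else rep(0, nrow(m))
    data.frame(
      l = cell$l, h = cell$h,
      quantity = rep(c("donation", "aspiration"), each = 11L),
      bin = rep(0:10, 2L),
      freq_mean = unname(c(rowMeans(hd), rowMeans(ha))),
      freq_sd = unname(c(sd0(hd), sd0(ha))),
      row.names = NULL
    )
  }
  cell_table <- do.call(rbind, lapply(cells, cell_frame))

  pooled_d <- unlist(lapply(all_runs, `[[`, "final_donations"),
                     use.names = FALSE)
  pooled_a <- unlist(lapply(all_runs, `[[`, "final_aspirations"),
                     use.names = FALSE)
  conv_steps <- vapply(all_runs, `[[`, numeric(1), "converged_at")
  structure(
    list(cell_table = cell_table,
         pooled_donations = pooled_d,
         pooled_aspirations = pooled_a,
         mean_donation = mean_donation(pooled_d),
         histogram_gini = histogram_gini(pooled_d, phi),
         equality_index = equality_index(pooled_d),
         gini = gini_coefficient(pooled_d),
         n_runs = length(all_runs),
         convergence_steps = conv_steps,
         n_converged = sum(vapply(all_runs, `[[`, logical(1), "converged")),
         endowment = phi, n_agents = n_agents),
    class = "dg_sweep"
  )
}

#' @export
print.dg_sweep <- function(x, ...) {
  n_cells <- nrow(unique(x$cell_table[, c("l", "h")]))
  cat(sprintf("Dictator Game sweep: %d cell(s) x %d run(s) total, N = %d\n",
              n_cells, x$n_runs, x$n_agents))
  cat(sprintf("  pooled mean donation <d>    : %.4f\n", x$mean_donation))
  cat(sprintf("  pooled concentration G      : %.4f (histogram Gini)\n",
              x$histogram_gini))
  cat(sprintf("  pooled equality index 1-Gini: %.4f (raw Gini %.4f)\n",
              x$equality_index, x$gini))
  cat(sprintf("  stationary runs          : %d / %d (median %d steps)\n",
              x$n_converged, x$n_runs,
              as.integer(stats::median(x$convergence_steps))))
  invisible(x)
}

#' Histogram panels of a sweep
#'
#' One panel per `(l, h)` cell showing the replication-averaged donation
#' (solid bars) and aspiration (hollow bars) histograms.
#'
#' @param x a `dg_sweep` object.
#' @param quantity which distributions to draw.
#' @param ... ignored.
#' @export
plot.dg_sweep <- function(x, quantity = c("both", "donation", "aspiration"),
                          ...) {
  quantity <- match.arg(quantity)
  tab <- x$cell_table
  cells <- unique(tab[, c("l", "h")])
  cells <- cells[order(cells$l, cells$h), , drop = FALSE]
  nr <- length(unique(cells$l))
  nc <- length(unique(cells$h))
  op <- graphics::par(mfrow = c(nr, nc), mar = c(2, 2, 1.5, 0.5))
  on.exit(graphics::par(op))
  for (k in seq_len(nrow(cells))) {
    sub <- tab[tab$l == cells$l[k] & tab$h == cells$h[k], ]
    don <- sub$freq_mean[sub$quantity == "donation"]
    asp <- sub$freq_mean[sub$quantity == "aspiration"]
    ymax <- max(don, asp, 0.1)
    if (quantity != "aspiration") {
      graphics::barplot(don, names.arg = 0:10, col = "steelblue",
                        border = NA, ylim = c(0, ymax),
                        main = sprintf("l=%g h=%g", cells$l[k], cells$h[k]),
                        cex.main = 0.8)
      if (quantity == "both")
        graphics::barplot(asp, add = TRUE, col = NA, border = "firebrick")
    } else {
      graphics::barplot(asp, names.arg = 0:10, col = "firebrick",
                        border = NA, ylim = c(0, ymax),
                        main = sprintf("l=%g h=%g", cells$l[k], cells$h[k]),
                        cex.main = 0.8)
    }
  }
  invisible(x)
}
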