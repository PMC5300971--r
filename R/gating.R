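#' Derive per-channel gating cutoffs automatically
#'
#' Two deterministic rules are available. `"midpoint"` finds the deepest
#' kernel-density valley between the two highest modes of a channel;
#' channels without two clear modes fall back to the fixed-quantile rule
#' (recorded in the result). `"quantile"` returns the given upper quantile,
#' suitable for dump/viability channels where genuine events form the low
#' mode.
#'
#' @param x An [event_matrix()] or numeric matrix.
#' @param channels Channels to derive cutoffs for.
#' @param rule `"midpoint"` or `"quantile"`.
#' @param q Quantile used by the `"quantile"` rule and the fallback.
#' @return Named numeric vector of cutoffs with attribute `"rule_used"`
#'   (per-channel rule actually applied).
#' @export
auto_thresholds <- function(x, channels = colnames(x),
                            rule = c("midpoint", "quantile"), q = 0.99) {
  rule <- match.arg(rule)
  bad <- setdiff(channels, colnames(x))
  if (length(bad)) stop("unknown channel(s): ", paste(bad, collapse = ", "))
  cuts <- numeric(length(channels))
  used <- character(length(channels))
  names(cuts) <- names(used) <- channels
  for (ch in channels) {
    v <- as.numeric(unclass(x)[, ch])
    if (rule == "quantile") {
      cuts[ch] <- stats::quantile(v, q, names = FALSE)
      used[ch] <- "quantile"
      next
    }
    valley <- .density_valley(v)
    if (is.na(valley)) {
      cuts[ch] <- stats::quantile(v, q, names = FALSE)
      used[ch] <- "quantile-fallback"
      message("auto_thresholds: channel ", ch,
              " has no two clear modes; fixed-quantile fallback used")
    } else {
      cuts[ch] <- valley
      used[ch] <- "midpoint"
    }
  }
  attr(cuts, "rule_used") <- used
  cuts
}

# deepest density valley between the two highest modes; NA when unimodal or
# degenerate. Peaks below 0.5% of the maximum density are sampling noise and
# ignored; the two modes must be separated by at least 4 bandwidths and the
# valley must drop below 20% of the lower mode, otherwise the channel is
# treated as unimodal.
.density_valley <- function(v) {
  if (length(unique(v)) < 2L || stats::sd(v) == 0) return(NA_real_)
  d <- stats::density(v, n = 512, adjust = 1.5)
  y <- d$y
  pk <- which(diff(sign(diff(y))) == -2) + 1L
  pk <- pk[y[pk] >= 0.005 * max(y)]
  if (length(pk) < 2L) return(NA_real_)
  top2 <- pk[order(y[pk], decreasing = TRUE)][1:2]
  lo <- min(top2); hi <- max(top2)
  if (d$x[hi] - d$x[lo] < 4 * d$bw) return(NA_real_)
  vi <- lo + which.min(y[lo:hi]) - 1L
  if (y[vi] > 0.2 * min(y[top2])) return(NA_real_)
  d$x[vi]
}

#' Gate events to the NK compartment
#'
#' Keeps viable, dump-negative events that fall in the CD56+CD16+,
#' CD56+CD16- or CD56-CD16+ quadrants; CD56-CD16- double-negative events
#' are excluded. An event is dump-negative when every dump channel (and the
#' viability channel) is at or below its cutoff; CD56/CD16 positivity means
#' strictly above the cutoff.
#'
#' @param x An [event_matrix()] with the panel channels.
#' @param thresholds Named numeric vector of cutoffs: one per dump channel,
#'   the viability channel, CD56 and CD16.
#' @param panel The [nk_panel()] naming the channels.
#' @return An object of class `nk_gate`: list with `kept` (1-based event
#'   indices into `x`), `gate_name`, `thresholds_used`, `quadrants`
#'   (per-quadrant event counts) and `n_input`.
#' @export
gate_nk <- function(x, thresholds, panel = nk_panel()) {
  stopifnot(is.numeric(thresholds), !is.null(names(thresholds)))
  need <- c(panel$dump_markers, panel$viability_marker, "CD56", "CD16")
  missing <- setdiff(need, names(thresholds))
  if (length(missing)) {
    stop("thresholds missing for channel(s): ", paste(missing, collapse = ", "))
  }
  m <- unclass(x)
  missing_ch <- setdiff(need, colnames(m))
  if (length(missing_ch)) {
    stop("event matrix lacks channel(s): ", paste(missing_ch, collapse = ", "))
  }
  for (ch in need) {
    rng <- range(m[, ch])
    if (nrow(m) > 0 && (thresholds[ch] < rng[1] || thresholds[ch] > rng[2])) {
      warning("gate_nk: threshold for ", ch,
              " lies outside the data range; gate may be empty or total")
    }
  }
  clean <- rep(TRUE, nrow(m))
  for (d in c(panel$dump_markers, panel$viability_marker)) {
    clean <- clean & m[, d] <= thresholds[d]
  }
  cd56 <- m[, "CD56"] > thresholds["CD56"]
  cd16 <- m[, "CD16"] > thresholds["CD16"]
  q_pp <- clean & cd56 & cd16
  q_pm <- clean & cd56 & !cd16
  q_mp <- clean & !cd56 & cd16
  kept <- which(q_pp | q_pm | q_mp)
  structure(
    list(kept = kept,
         gate_name = "NK (dump- viable CD56/CD16 union)",
         thresholds_used = thresholds[need],
         quadrants = c("CD56+CD16+" = sum(q_pp), "CD56+CD16-" = sum(q_pm),
                       "CD56-CD16+" = sum(q_mp)),
         n_input = nrow(m)),
    class = "nk_gate"
  )
}

#' @export
print.nk_gate <- function(x, ...) {
  cat("<nk_gate> ", x$gate_name, ": kept ", length(x$kept), " / ",
      x$n_input, " events\n", sep = "")
  print(x$quadrants)
  invisible(x)
}

#' Apply a gate to an event matrix
#'
#' @param x The [event_matrix()] the gate was computed on.
#' @param gate An `nk_gate` from [gate_nk()].
#' @return The gated [event_matrix()].
#' @export
apply_gate <- function(x, gate) {
  stopifnot(inherits(gate, "nk_gate"))
  x[gate$kept, , drop = FALSE]
}

#' Default gate thresholds for pipeline data
#'
#' Dump and viability cutoffs come from [auto_thresholds()] (density-valley
#' rule with quantile fallback); CD56/CD16 positivity cutoffs sit between
#' the negative and low expression levels of the transformed scale.
#'
#' @param x An [event_matrix()].
#' @param panel Marker panel.
#' @param cd56_cut,cd16_cut Positivity cutoffs on the transformed scale
#'   (default 0.5, between the `neg` = 0 and `low` = 1 grid levels).
#' @return Named numeric vector of thresholds for [gate_nk()].
#' @export
default_gate_thresholds <- function(x, panel = nk_panel(),
                                    cd56_cut = 0.5, cd16_cut = 0.5) {
  dump <- suppressMessages(
    auto_thresholds(x, c(panel$dump_markers, panel$viability_marker),
                    rule = "midpoint", q = 0.995))
  c(dump, CD56 = cd56_cut, CD16 = cd16_cut)
}

#' Write a gate audit log
#'
#' Tab-delimited record of the gate: thresholds used, per-quadrant counts
#' and the kept event indices (0-based in the interchange file).
#'
#' @param gate An `nk_gate`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gate_log <- function(gate, path) {
  stopifnot(inherits(gate, "nk_gate"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# gate=", gate$gate_name), con)
  writeLines(paste("threshold", names(gate$thresholds_used),
                   gate$thresholds_used, sep = "\t"), con)
  writeLines(paste("quadrant", names(gate$quadrants), gate$quadrants,
                   sep = "\t"), con)
  writeLines(paste("kept_index", gate$kept - 1L, sep = "\t"), con)
  invisible(path)
}
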