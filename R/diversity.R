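## Clade diversity through time: every branch of a time-scaled tree is a
## lineage segment [parent age, end], where end is the child node age for
## internal branches and the tip's record end (LAD by default, FAD
## optionally) for terminal branches. Zero-duration internal segments
## (cladogenesis points) are not lineages and are dropped; zero-duration
## terminal segments (point occurrences) are kept.

lineage_segments <- function(ts, use_lad = TRUE) {
  phy <- ts$tree
  ntip <- length(phy$tip.label)
  start <- end <- numeric(nrow(phy$edge))
  is_tip <- phy$edge[, 2] <= ntip
  for (k in seq_len(nrow(phy$edge))) {
    p <- phy$edge[k, 1]; ch <- phy$edge[k, 2]
    start[k] <- ts$node_age[p]
    end[k] <- if (ch <= ntip) {
      if (use_lad) ts$lad[ch] else ts$fad[ch]
    } else ts$node_age[ch]
  }
  keep <- is_tip | (start - end) > 1e-12
  data.frame(edge = seq_len(nrow(phy$edge)), start = start, end = end,
             tip = is_tip)[keep, ]
}

## which segments belong to a clade spec: a branch is counted when all its
## descendant tips lie in `include` (default: all tips) and NOT all of them
## lie in `exclude`. With this rule a clade and its complement partition
## the branches exactly: "exclude = clade" drops precisely the branches
## inside the clade (its stem included), and keeps everything else.
segments_in_spec <- function(ts, include = NULL, exclude = NULL) {
  phy <- ts$tree
  tips <- phy$tip.label
  S <- include %||% tips
  miss <- setdiff(c(S, exclude), tips)
  if (length(miss)) stop_labeled("unknown taxa in clade spec: ",
                                 paste(miss, collapse = ", "))
  if (!length(setdiff(S, exclude))) stop_labeled("clade spec selects no taxa")
  dt <- descendant_tips(phy)
  seg <- lineage_segments(ts)
  inset <- vapply(seg$edge, function(k) {
    below <- tips[dt[[phy$edge[k, 2]]]]
    all(below %in% S) &&
      !(length(exclude) && all(below %in% exclude))
  }, logical(1))
  seg[inset, ]
}

#' Lineages crossing a time point
#'
#' Counts the branches (observed ranges plus ghost segments) of the
#' selected clade subset whose durations cross time `t`.
#'
#' @param ts a `timescaled_tree`.
#' @param t time in Ma.
#' @param include optional character vector of tip labels: only branches
#'   all of whose descendants are in this set are counted.
#' @param exclude optional tip labels removed from the set (e.g. a whole
#'   subclade, for "clade X without clade Y" counts).
#' @return integer count.
#' @export
lineage_count <- function(ts, t, include = NULL, exclude = NULL) {
  stopifnot(t >= 0)
  seg <- segments_in_spec(ts, include, exclude)
  sum(seg$start >= t & seg$end <= t)
}

#' Clade diversity-through-time curve
#'
#' Bins the time axis into contiguous half-open intervals `[t_old,
#' t_young)` and counts, per bin, the distinct lineages of the selected
#' clade subset whose durations intersect the bin. A lineage is counted
#' once per bin regardless of overlap fraction.
#'
#' @inheritParams lineage_count
#' @param bin_width bin width in Myr.
#' @param from oldest bin edge in Ma (default: root age rounded up to a
#'   bin edge).
#' @param to youngest edge (default 0).
#' @param label curve label.
#' @return object of class `diversity_curve`: data.frame with `t_old`,
#'   `t_young`, `count`.
#' @export
diversity_curve <- function(ts, bin_width = 1, include = NULL,
                            exclude = NULL, from = NULL, to = 0,
                            label = "all") {
  stopifnot(bin_width > 0)
  seg <- segments_in_spec(ts, include, exclude)
  from <- from %||% (bin_width * ceiling(ts$root_age / bin_width))
  edges <- seq(from, to, by = -bin_width)
  if (length(edges) < 2) stop_labeled("time window shorter than one bin")
  t_old <- edges[-length(edges)]
  t_young <- edges[-1]
  count <- vapply(seq_along(t_old), function(i)
    sum(seg$start > t_young[i] & seg$end <= t_old[i]), integer(1))
  structure(data.frame(t_old = t_old, t_young = t_young, count = count),
            class = c("diversity_curve", "data.frame"),
            label = label, bin_width = bin_width)
}

#' @export
print.diversity_curve <- function(x, ...) {
  cat(sprintf("Diversity curve '%s': %d bins of %g Myr, max %d lineages\n",
              attr(x, "label"), nrow(x), attr(x, "bin_width"),
              max(x$count)))
  NextMethod()
}

#' @export
plot.diversity_curve <- function(x, ...) {
  plot.new()
  plot.window(xlim = c(max(x$t_old), min(x$t_young)),
              ylim = c(0, max(x$count) + 1))
  axis(1); axis(2)
  title(xlab = "age (Ma)", ylab = "lineages",
        main = attr(x, "label"))
  xs <- as.vector(rbind(x$t_old, x$t_young))
  ys <- as.vector(rbind(x$count, x$count))
  lines(xs, ys, type = "l")
  invisible(x)
}

#' Detect diversity pulses (radiations)
#'
#' Scans a diversity curve oldest-first for windows of monotone count
#' increase: maximal non-decreasing runs are split into windows of span
#' at most `max_span`, and windows whose total rise reaches `min_rise`
#' are reported as events, oldest first and non-overlapping.
#'
#' @param curve a [diversity_curve].
#' @param min_rise minimum count increase (>= 1).
#' @param max_span maximum window span in Myr.
#' @return data.frame of class `diversity_events` with `start` (older
#'   edge, Ma), `end`, `rise` and `label`.
#' @export
detect_pulses <- function(curve, min_rise = 3, max_span = 3) {
  stopifnot(min_rise >= 1, max_span > 0)
  n <- nrow(curve)
  events <- list()
  flush <- function(i0, i1) {
    # bins i0..i1 hold a monotone rise; cut into <= max_span windows
    while (i0 <= i1) {
      j <- i0
      while (j < i1 && (curve$t_old[i0] - curve$t_young[j + 1]) <= max_span)
        j <- j + 1
      base <- if (i0 > 1) curve$count[i0 - 1] else curve$count[i0]
      rise <- curve$count[j] - base
      if (rise >= min_rise)
        events[[length(events) + 1]] <<- data.frame(
          start = curve$t_old[i0], end = curve$t_young[j], rise = rise)
      i0 <- j + 1
    }
  }
  i <- 2
  run_start <- NA
  last_rise <- NA
  while (i <= n) {
    if (curve$count[i] > curve$count[i - 1]) {
      if (is.na(run_start)) run_start <- i
      last_rise <- i
    } else if (curve$count[i] < curve$count[i - 1]) {
      if (!is.na(run_start)) { flush(run_start, last_rise); run_start <- NA }
    }
    i <- i + 1
  }
  if (!is.na(run_start)) flush(run_start, last_rise)
  out <- if (length(events)) do.call(rbind, events)
         else data.frame(start = numeric(), end = numeric(),
                         rise = numeric())
  out$label <- if (nrow(out)) paste0("event_", seq_len(nrow(out))) else character(0)
  class(out) <- c("diversity_events", "data.frame")
  out
}
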