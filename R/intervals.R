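# Half-open integer-day intervals [start, end), the engine behind coverage,
# PDC and persistence arithmetic. All dates are converted to integer days
# (days since 1970-01-01) at the boundary; no times, no time zones.

empty_iv <- function() data.frame(start = integer(), end = integer())

as_iv <- function(start, end) {
  if (length(start) != length(end)) stop("start/end length mismatch")
  if (any(end <= start)) stop("intervals must satisfy end > start")
  data.frame(start = as.integer(start), end = as.integer(end))
}

# Union of possibly overlapping intervals -> disjoint, sorted.
iv_merge <- function(x) {
  n <- nrow(x)
  if (n <= 1L) return(x[, c("start", "end"), drop = FALSE])
  x <- x[order(x$start, x$end), , drop = FALSE]
  ce <- cummax(x$end)
  new_run <- c(TRUE, x$start[-1L] > ce[-n])
  g <- cumsum(new_run)
  data.frame(start = x$start[new_run],
             end = as.integer(tapply(x$end, g, max)))
}

# Restrict to [lo, hi), dropping emptied intervals.
iv_clip <- function(x, lo, hi) {
  if (nrow(x) == 0L) return(x)
  s <- pmax(x$start, as.integer(lo))
  e <- pmin(x$end, as.integer(hi))
  keep <- e > s
  data.frame(start = s[keep], end = e[keep])
}

iv_total <- function(x) if (nrow(x) == 0L) 0L else sum(x$end - x$start)

# Days on which at least k of the given interval sets are simultaneously
# active, via a boundary sweep. Each element of `sets` is merged first so a
# set never counts twice on the same day.
iv_atleast <- function(sets, k) {
  sets <- lapply(sets, iv_merge)
  sets <- Filter(nrow, sets)
  if (length(sets) < k) return(empty_iv())
  st <- unlist(lapply(sets, `[[`, "start"), use.names = FALSE)
  en <- unlist(lapply(sets, `[[`, "end"), use.names = FALSE)
  t <- c(st, en)
  d <- c(rep(1L, length(st)), rep(-1L, length(en)))
  o <- order(t)
  t <- t[o]; d <- d[o]
  cs <- cumsum(d)
  last <- !duplicated(t, fromLast = TRUE)   # net count after all events at t
  tt <- t[last]; cc <- cs[last]
  n <- length(tt)
  if (n < 2L) return(empty_iv())
  act <- cc[-n] >= k                        # active on [tt_i, tt_{i+1})
  if (!any(act)) return(empty_iv())
  iv_merge(data.frame(start = tt[-n][act], end = tt[-1L][act]))
}

iv_intersect <- function(a, b) iv_atleast(list(a, b), 2L)

# TRUE if `day` lies inside some interval of the (merged, sorted) set.
iv_contains <- function(x, day) {
  if (nrow(x) == 0L) return(FALSE)
  i <- findInterval(day, x$start)
  i >= 1L && day < x$end[i]
}
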