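#' Risk-set calendar intervals
#'
#' The follow-up 1999-2008 is divided into four calendar risk sets, each
#' assigned the cumulative mean of the model-year exposures available up to
#' its start: 1999-2002 uses 1999; 2003-2004 the mean of 1999 and 2003;
#' 2005-2006 the mean of 1999, 2003 and 2005; 2007-2008 the mean of all four
#' model years.
#'
#' @return data.frame with `interval`, `start`, `end` (Dates) and a list
#'   column `years` of contributing model years.
#' @export
risk_set_intervals <- function() {
  out <- data.frame(
    interval = c("1999-2002", "2003-2004", "2005-2006", "2007-2008"),
    start = as.Date(c("1999-01-01", "2003-01-01", "2005-01-01", "2007-01-01")),
    end = as.Date(c("2002-12-31", "2004-12-31", "2006-12-31", "2008-12-31")),
    stringsAsFactors = FALSE)
  out$years <- list(1999L, c(1999L, 2003L), c(1999L, 2003L, 2005L),
                    c(1999L, 2003L, 2005L, 2007L))
  out
}

model_years <- c(1999L, 2003L, 2005L, 2007L)

DAYS_PER_YEAR <- 365.25

#' Age class of a continuous age
#'
#' @param age age in years.
#' @param width class width in years (default 5-year bands).
#' @return character labels like `"45-49"`.
#' @export
age_class <- function(age, width = 5) {
  k <- floor(age / width)
  sprintf("%d-%d", k * width, (k + 1) * width - 1)
}

# Split each subject's follow-up window at risk-set boundaries and age-class
# boundaries. `subjects` needs subject_id, municipality_id, household_id,
# birth_date, enroll_date. Returns one row per (subject, interval) with
# tstart/tstop as numeric days (unclass(Date)), riskset and age_class.
split_follow_up <- function(subjects, window, age_width = 5,
                            end_override = NULL) {
  rs <- risk_set_intervals()
  w0 <- as.numeric(as.Date(window[1]))
  w1 <- as.numeric(as.Date(window[2])) + 1  # end is inclusive; stop is exclusive
  birth <- as.numeric(subjects$birth_date)
  start <- pmax(as.numeric(subjects$enroll_date), w0)
  end <- rep(w1, nrow(subjects))
  if (!is.null(end_override)) end <- pmin(end, end_override)
  keep <- start < end
  idx <- which(keep)
  n <- length(idx)
  if (n == 0) stop("no subject has follow-up inside the window")
  start <- start[idx]; end <- end[idx]; birth <- birth[idx]
  # age-class boundary dates strictly inside (start, end)
  aw <- age_width * DAYS_PER_YEAR
  k_min <- floor((start - birth) / aw) + 1
  k_max <- ceiling((end - birth) / aw) - 1
  nk <- pmax(k_max - k_min + 1, 0)
  srow <- rep(seq_len(n), nk)
  kk <- sequence(nk) - 1 + rep(k_min, nk)
  age_breaks <- data.frame(row = srow, t = birth[srow] + kk * aw)
  age_breaks <- age_breaks[age_breaks$t > start[srow] &
                             age_breaks$t < end[srow], ]
  # risk-set boundary dates inside (start, end)
  rb <- as.numeric(rs$start[-1])
  rs_breaks <- data.frame(row = rep(seq_len(n), each = length(rb)),
                          t = rep(rb, times = n))
  rs_breaks <- rs_breaks[rs_breaks$t > start[rs_breaks$row] &
                           rs_breaks$t < end[rs_breaks$row], ]
  pts <- rbind(data.frame(row = seq_len(n), t = start), age_breaks, rs_breaks)
  pts <- pts[!duplicated(pts), ]
  pts <- pts[order(pts$row, pts$t), ]
  m <- nrow(pts)
  nxt_same <- c(pts$row[-1] == pts$row[-m], FALSE)
  tstop <- ifelse(nxt_same, c(pts$t[-1], NA), end[pts$row])
  mid <- (pts$t + tstop) / 2
  out <- data.frame(
    subject_id = subjects$subject_id[idx][pts$row],
    municipality_id = subjects$municipality_id[idx][pts$row],
    household_id = subjects$household_id[idx][pts$row],
    tstart = pts$t, tstop = tstop,
    age_class = age_class((mid - birth[pts$row]) / DAYS_PER_YEAR,
                          width = age_width),
    riskset = rs$interval[findInterval(mid, as.numeric(rs$start))],
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# Draw one event time per subject from a piecewise-constant hazard laid out
# as follow-up rows with a `rate` column (events per person-year). Returns a
# numeric vector (days) aligned with unique(subject_id); NA = no event before
# the end of the rows. Rows must be sorted by subject and tstart.
sim_piecewise_exponential <- function(rows, rate) {
  sid <- factor(rows$subject_id, levels = unique(rows$subject_id))
  dur <- (rows$tstop - rows$tstart) / DAYS_PER_YEAR
  h <- rate * dur
  cum <- stats::ave(h, sid, FUN = cumsum)
  cum_before <- cum - h
  e <- stats::rexp(nlevels(sid))[as.integer(sid)]
  hit <- e > cum_before & e <= cum & rate > 0
  tt <- rep(NA_real_, nlevels(sid))
  tt[as.integer(sid)[hit]] <-
    rows$tstart[hit] + (e[hit] - cum_before[hit]) / rate[hit] * DAYS_PER_YEAR
  tt
}
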