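# Conservative epoch-based region growing. Around each boundary pixel of
# the current region R an m x m window is inspected; only when R already
# dominates the window (> eta percent membership) may the window recruit:
# its local threshold is t1 = me1 + std1 over the non-background grays,
# and outside pixels at or above t1 join R. One full boundary sweep is an
# epoch; growing repeats while the epoch growth rate
# (E_c - E_p) / E_c * 100 stays positive.

#' Region-growing configuration
#'
#' @param m odd window side (default 3, shared with the rule stage).
#' @param eta pixel factor in percent (default 50): minimum window
#'   membership before a window may recruit. Lower values over-segment;
#'   higher values leave hemorrhage pixels behind.
#' @param max_epochs safety cap on epochs (growth already guarantees
#'   termination; the cap is belt-and-braces).
#' @param dominance `"membership"` counts window pixels already in R
#'   (default); `"in_range"` counts window pixels with gray >= G_opt.
#' @return object of class `grow_config`.
#' @export
grow_config <- function(m = 3L, eta = 50, max_epochs = 100L,
                        dominance = c("membership", "in_range")) {
  if (m %% 2L == 0L) stop("grow window size m must be odd")
  if (eta <= 0 || eta >= 100) stop("eta must lie in (0, 100)")
  structure(list(m = as.integer(m), eta = eta,
                 max_epochs = as.integer(max_epochs),
                 dominance = match.arg(dominance)),
            class = "grow_config")
}

#' Local recruiting threshold of a window
#'
#' `t1 = me1 + std1`, where `me1`/`std1` are the mean and population
#' standard deviation of the window's non-background (gray > 0) pixels;
#' the background set is excluded from the divisor.
#'
#' @param window numeric matrix or vector of window gray levels.
#' @return `t1`, or `NA` when the window is entirely background (such a
#'   window is skipped by the grower).
#' @export
window_threshold <- function(window) {
  v <- as.vector(window)
  v <- v[v > 0]
  if (!length(v)) return(NA_real_)
  me1 <- mean(v)
  std1 <- sqrt(mean((v - me1)^2))
  me1 + std1
}

#' Grow the hemorrhage region to a fixed point
#'
#' Epochs sweep the current boundary; additions are collected during the
#' sweep and applied afterwards (synchronous update), so the epoch areas
#' `E_p`/`E_c` and the growth rate are well defined. The region area is
#' non-decreasing and bounded by the image, so the process halts.
#'
#' @param r non-empty starting `region_mask` (the rule-stage region).
#' @param slice masked `ct_slice`.
#' @param g_opt optimum minimum hemorrhage gray (used only for the
#'   `"in_range"` dominance reading).
#' @param cfg `grow_config`.
#' @return list: `mask` (final `region_mask`) and `trace` (data.frame with
#'   one row per epoch: `epoch`, `e_p`, `e_c`, `growth_rate`, `added`).
#' @export
grow_region <- function(r, slice, g_opt, cfg = grow_config()) {
  rm <- as_mask_matrix(r)
  if (!any(rm)) stop("cannot grow an empty region")
  half <- cfg$m %/% 2L
  h <- slice$height; w <- slice$width
  px <- slice$pixels
  trace <- list()
  epoch <- 0L
  repeat {
    epoch <- epoch + 1L
    e_p <- sum(rm)
    tb <- extract_boundary(rm)
    add <- matrix(FALSE, h, w)
    for (k in seq_len(nrow(tb))) {
      win <- window_range(tb[k, 1], tb[k, 2], half, h, w)
      grays <- px[win$rows, win$cols, drop = FALSE]
      dom <- if (cfg$dominance == "membership") {
        rm[win$rows, win$cols, drop = FALSE]
      } else {
        grays >= g_opt
      }
      if (100 * mean(dom) <= cfg$eta) next
      t1 <- window_threshold(grays)
      if (is.na(t1)) next
      pass <- !rm[win$rows, win$cols, drop = FALSE] & grays > 0L &
        grays >= t1
      if (any(pass)) {
        rr <- matrix(win$rows, length(win$rows), length(win$cols))
        cc <- matrix(win$cols, length(win$rows), length(win$cols),
                     byrow = TRUE)
        add[cbind(rr[pass], cc[pass])] <- TRUE
      }
    }
    rm <- rm | add
    e_c <- sum(rm)
    growth <- (e_c - e_p) / e_c * 100
    trace[[epoch]] <- data.frame(epoch = epoch, e_p = e_p, e_c = e_c,
                                 growth_rate = growth, added = e_c - e_p)
    if (growth <= 0 || epoch >= cfg$max_epochs) break
  }
  list(mask = region_mask(rm, "segmented_hemorrhage", slice$id),
       trace = do.call(rbind, trace))
}
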