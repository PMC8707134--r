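#' Generate a two-way split-plot trial design
#'
#' Builds the geometry and randomization of a split-plot trial laid out on
#' parallel beds: each block is one bed, split lengthwise into two halves
#' (separated by a tunnel gap) that receive the two levels of the main-plot
#' factor; each half is divided into one plot per sub-plot factor level.
#' Measurement spots are placed on a regular grid inside every plot.
#'
#' The default arguments reproduce the canonical layout used throughout the
#' package: 4 blocks x 2 main-plot levels x 5 sub-plot levels = 40 plots of
#' 3.0 x 1.3 m, each carrying 12 spots spaced 0.5 m apart on a 6 x 2 grid
#' centered in the plot.
#'
#' @param n_blocks Number of blocks (beds). Default 4.
#' @param main_levels Labels of the main-plot factor (one per block half).
#'   Must have length 1 or 2.
#' @param sub_levels Labels of the sub-plot factor (one plot per level within
#'   each half).
#' @param plot_w,plot_d Plot width (along the bed) and depth (across the bed)
#'   in metres.
#' @param spots_per_plot Number of measurement spots per plot; must be
#'   expressible as an `nc x nr` grid at `spacing` that fits inside the plot.
#' @param spacing Spot grid spacing in metres.
#' @param alley Gap between adjacent beds in metres.
#' @param tunnel_gap Gap between the two halves of each block along the bed
#'   axis, in metres.
#' @param seed Integer seed driving the randomization of factor levels.
#'
#' @return An object of class `trial_design`: a list with data frames
#'   `plots` (plot, block, half, main, sub, x0, y0, w, d) and `spots`
#'   (spot, plot, block, half, main, sub, x, y), plus the generating
#'   parameters.
#' @export
#' @examples
#' d <- generate_design(seed = 1)
#' nrow(d$plots) # 40
#' nrow(d$spots) # 480
generate_design <- function(n_blocks = 4,
                            main_levels = c("NO", "YES"),
                            sub_levels = c("TRI", "LAM", "CER", "CHE", "CTR"),
                            plot_w = 3.0, plot_d = 1.3,
                            spots_per_plot = 12, spacing = 0.5,
                            alley = 0.5, tunnel_gap = 2.0,
                            seed = 1L) {
  stopifnot(n_blocks >= 1, plot_w > 0, plot_d > 0, spacing > 0,
            length(main_levels) %in% c(1L, 2L), length(sub_levels) >= 1,
            !anyDuplicated(main_levels), !anyDuplicated(sub_levels))
  grid <- spot_grid_dims(plot_w, plot_d, spots_per_plot, spacing)
  n_main <- length(main_levels)
  n_sub <- length(sub_levels)

  plots <- withr::with_seed(seed, {
    out <- vector("list", n_blocks)
    for (b in seq_len(n_blocks)) {
      mains <- if (n_main == 2) sample(main_levels) else main_levels
      halves <- lapply(seq_len(n_main), function(h) {
        subs <- sample(sub_levels)
        x0 <- (h - 1) * (n_sub * plot_w + tunnel_gap) +
          (seq_len(n_sub) - 1) * plot_w
        data.frame(block = b, half = h, main = mains[h], sub = subs,
                   x0 = x0, y0 = (b - 1) * (plot_d + alley),
                   stringsAsFactors = FALSE)
      })
      out[[b]] <- do.call(rbind, halves)
    }
    do.call(rbind, out)
  })
  plots$plot <- seq_len(nrow(plots))
  plots$w <- plot_w
  plots$d <- plot_d
  plots <- plots[c("plot", "block", "half", "main", "sub", "x0", "y0", "w", "d")]

  # spot grid centered in the plot rectangle
  gx <- (seq_len(grid[1]) - 1) * spacing
  gy <- (seq_len(grid[2]) - 1) * spacing
  off_x <- (plot_w - max(gx)) / 2
  off_y <- (plot_d - max(gy)) / 2
  local_xy <- expand.grid(x = gx + off_x, y = gy + off_y)

  spots <- plots[rep(seq_len(nrow(plots)), each = nrow(local_xy)),
                 c("plot", "block", "half", "main", "sub", "x0", "y0")]
  spots$x <- spots$x0 + rep(local_xy$x, nrow(plots))
  spots$y <- spots$y0 + rep(local_xy$y, nrow(plots))
  spots$x0 <- spots$y0 <- NULL
  spots$spot <- seq_len(nrow(spots))
  rownames(spots) <- NULL
  spots <- spots[c("spot", "plot", "block", "half", "main", "sub", "x", "y")]

  structure(list(plots = plots, spots = spots,
                 main_levels = main_levels, sub_levels = sub_levels,
                 plot_w = plot_w, plot_d = plot_d, spacing = spacing,
                 grid = grid, alley = alley, tunnel_gap = tunnel_gap,
                 seed = seed),
            class = "trial_design")
}

# choose the widest nc x nr factorization of k that fits the plot
spot_grid_dims <- function(plot_w, plot_d, k, spacing) {
  stopifnot(k >= 1)
  for (nc in sort(which(k %% seq_len(k) == 0), decreasing = TRUE)) {
    nr <- k %/% nc
    if ((nc - 1) * spacing <= plot_w + 1e-9 &&
        (nr - 1) * spacing <= plot_d + 1e-9) {
      return(c(nc = nc, nr = nr))
    }
  }
  stop("no ", k, "-spot grid at spacing ", spacing,
       " m fits a ", plot_w, " x ", plot_d, " m plot")
}

#' @export
print.trial_design <- function(x, ...) {
  cat("Split-plot trial design\n")
  cat("  blocks:", length(unique(x$plots$block)),
      " plots:", nrow(x$plots), " spots:", nrow(x$spots), "\n")
  cat("  main-plot levels:", paste(x$main_levels, collapse = ", "), "\n")
  cat("  sub-plot levels: ", paste(x$sub_levels, collapse = ", "), "\n")
  cat("  plot:", x$plot_w, "x", x$plot_d, "m; spot grid",
      x$grid[1], "x", x$grid[2], "at", x$spacing, "m\n")
  invisible(x)
}
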