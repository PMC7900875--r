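#' Subsampling design for saturation analysis
#'
#' @param sizes strictly increasing positive subsample sizes. The default
#'   (30,000 to 150,000 in steps of 30,000) matches deep Iso-Seq consensus
#'   pools; synthetic runs use smaller sizes.
#' @param replicates replicates per size (default 3).
#' @param seed integer seed for the subsampling RNG.
#' @return object of class \code{saturation_design}.
#' @export
saturation_design <- function(sizes = seq(30000, 150000, by = 30000),
                              replicates = 3L, seed = 1L) {
  if (any(sizes <= 0) || any(diff(sizes) <= 0))
    .stopf("sizes must be strictly increasing and positive")
  if (!.is_count(replicates)) .stopf("replicates must be >= 1")
  structure(list(sizes = sizes, replicates = as.integer(replicates),
                 seed = as.integer(seed)), class = "saturation_design")
}

#' Build a subsample counter from a full phasing run
#'
#' Phasing is per-isoform independent, so counts for any isoform subsample
#' can be read off a full-pool assignment table instead of re-aligning.
#'
#' @param assignments an \code{isoform_assignments} data frame for the full
#'   pool.
#' @return function taking a vector of isoform ids and returning
#'   \code{c(y1, y2)}: expressed orthogroups and H_MP orthogroups.
#' @export
make_assignment_counter <- function(assignments) {
  force(assignments)
  function(ids) {
    sub <- assignments[assignments$isoform_id %in% ids, , drop = FALSE]
    sub$sample <- "pool"
    tab <- tabulate_homeologs(sub)
    if (!nrow(tab)) return(c(y1 = 0, y2 = 0))
    c(y1 = tab$total[1], y2 = tab$H_MP[1])
  }
}

#' Subsample an isoform pool and count discovered orthogroup classes
#'
#' Draws uniform without-replacement subsamples of each design size
#' (replicated) from the isoform pool and evaluates a counter on each:
#' \code{y1} = expressed orthogroups, \code{y2} = orthogroups with both
#' homeologs expressed (H_MP). Sizes exceeding the pool are skipped with a
#' warning.
#'
#' @param pool_ids character vector of isoform ids in the pool.
#' @param design a [saturation_design()].
#' @param counter function of ids returning \code{c(y1, y2)}, e.g.
#'   [make_assignment_counter()].
#' @return data frame with \code{size}, \code{replicate}, \code{y1},
#'   \code{y2}.
#' @export
subsample_counts <- function(pool_ids, design, counter) {
  stopifnot(inherits(design, "saturation_design"))
  sizes <- design$sizes
  drop <- sizes > length(pool_ids)
  if (any(drop)) {
    warning(sprintf("skipping %d size(s) larger than the pool (%d isoforms)",
                    sum(drop), length(pool_ids)))
    sizes <- sizes[!drop]
  }
  set.seed(design$seed)
  rows <- list()
  for (x in sizes) {
    for (r in seq_len(design$replicates)) {
      y <- counter(sample(pool_ids, x))
      rows[[length(rows) + 1L]] <- data.frame(size = x, replicate = r,
                                              y1 = y[["y1"]], y2 = y[["y2"]])
    }
  }
  do.call(rbind, rows)
}

#' Fit a degree-2 polynomial in log-log space
#'
#' Ordinary least squares of \code{log(y) = a (log x)^2 + b log x + c} over
#' all replicate points jointly. When the curvature is negative the vertex
#' \code{-b/(2a)} gives the transcript depth (on the log scale) at which
#' discovery saturates, and the fitted value there is the saturation value.
#'
#' @param points data frame with columns \code{size} and one of \code{y1}
#'   or \code{y2} selected via \code{response}.
#' @param response name of the count column to fit (default \code{"y1"}).
#' @param log_base base of the logarithm (default natural log; use 10 for
#'   decimal logs — vertex location in x and fitted counts are invariant to
#'   the choice).
#' @return object of class \code{saturation_fit}: list with \code{a},
#'   \code{b}, \code{c}, \code{log_base}, \code{vertex_log_x},
#'   \code{saturation_value} (NA when \code{a >= 0}), and the \code{lm}
#'   fit.
#' @export
fit_loglog_quadratic <- function(points, response = "y1", log_base = exp(1)) {
  y <- points[[response]]
  x <- points$size
  keep <- y > 0
  if (any(!keep)) {
    warning(sprintf("dropping %d point(s) with non-positive counts", sum(!keep)))
    x <- x[keep]; y <- y[keep]
  }
  if (length(unique(x)) < 3) .stopf("need >= 3 distinct sizes with positive counts")
  lx <- log(x, base = log_base)
  ly <- log(y, base = log_base)
  fit <- lm(ly ~ lx + I(lx^2))
  cf <- coef(fit)
  a <- unname(cf[["I(lx^2)"]]); b <- unname(cf[["lx"]]); c0 <- unname(cf[["(Intercept)"]])
  vertex <- if (a < 0) -b / (2 * a) else NA_real_
  sat <- if (a < 0) log_base^(a * vertex^2 + b * vertex + c0) else NA_real_
  structure(list(a = a, b = b, c = c0, log_base = log_base,
                 vertex_log_x = vertex, saturation_value = sat, lm = fit),
            class = "saturation_fit")
}

#' Predict a count from a saturation fit
#'
#' @param fit a [fit_loglog_quadratic()] result (or a list with \code{a},
#'   \code{b}, \code{c}, \code{log_base}).
#' @param x positive transcript counts.
#' @return predicted counts on the original scale.
#' @export
predict_saturation <- function(fit, x) {
  stopifnot(all(x > 0))
  lx <- log(x, base = fit$log_base)
  fit$log_base^(fit$a * lx^2 + fit$b * lx + fit$c)
}

#' Vertex of a printed log-log quadratic
#'
#' Closed-form saturation location \code{-b/(2a)} for coefficients of
#' \code{log(y) = a (log x)^2 + b log x + c}; independent of the log base.
#'
#' @param a,b quadratic and linear coefficients.
#' @return \code{-b/(2a)}.
#' @export
quadratic_vertex <- function(a, b) {
  if (a >= 0) .stopf("vertex defined only for negative curvature")
  -b / (2 * a)
}
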