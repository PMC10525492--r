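#' Activation maximization and scalp topography
#'
#' Activation maximization (AM) synthesizes the input pattern a trained
#' classifier most associates with a class: starting from small Gaussian
#' noise, it ascends the gradient of the target unit's pre-softmax logit
#' (softmax saturates gradients) with an L2 penalty, and averages the
#' resulting patterns over independent runs. Per-electrode energies of the
#' pattern are projected on a schematic head as a topographic map.
#'
#' @name interpretability
NULL

#' Activation maximization of one output unit
#'
#' Each run initializes the input from `N(0, init_sd^2)` and performs
#' `steps` gradient-ascent updates on
#' `logit(class) - l2_decay * ||x||^2`. The step size is halved (up to 10
#' times) whenever a step fails to increase the objective, so the
#' accepted-objective sequence is non-decreasing. The returned pattern is
#' the mean over runs.
#'
#' @param model an object with a [logit_and_gradient] method
#' @param class_index 1-based output unit
#' @param input_shape tensor shape (taken from the model when absent)
#' @param n_runs independent restarts averaged
#' @param steps gradient steps per run
#' @param step_size initial ascent step
#' @param l2_decay L2 penalty coefficient
#' @param init_sd initialization scale
#' @param nonneg constrain the pattern to the nonnegative orthant
#'   (projected ascent). The pipeline's inputs are magnitude spectra, so
#'   prototypes for spectro-tensor models should live in the valid input
#'   domain; unconstrained ascent drifts into directions no real input
#'   occupies
#' @param seed integer seed
#' @return an `am_pattern`: list with `pattern` (mean tensor), `class_index`,
#'   `final_activation` (mean final logit over runs), `activations` per run
#' @export
activation_maximization <- function(model, class_index,
                                    input_shape = model$input_shape,
                                    n_runs = 100L, steps = 256L,
                                    step_size = 0.1, l2_decay = 1e-3,
                                    init_sd = 0.01, nonneg = FALSE,
                                    seed = 1L) {
  acc <- array(0, dim = input_shape)
  finals <- numeric(n_runs)
  trace <- NULL
  with_seed(seed, {
    for (r in seq_len(n_runs)) {
      x <- array(stats::rnorm(prod(input_shape), sd = init_sd),
                 dim = input_shape)
      if (nonneg) x <- abs(x)
      lg <- logit_and_gradient(model, x, class_index)
      obj <- lg$value - l2_decay * sum(x^2)
      objs <- obj
      eta <- step_size
      halvings <- 0L
      for (s in seq_len(steps)) {
        g <- array(lg$grad, dim = input_shape) - 2 * l2_decay * x
        x_new <- x + eta * g
        if (nonneg) x_new <- pmax(x_new, 0)
        lg_new <- logit_and_gradient(model, x_new, class_index)
        obj_new <- lg_new$value - l2_decay * sum(x_new^2)
        if (obj_new >= obj) {
          x <- x_new; lg <- lg_new; obj <- obj_new
          objs <- c(objs, obj)
        } else if (halvings < 10L) {
          eta <- eta / 2; halvings <- halvings + 1L
        } else break
      }
      acc <- acc + x
      finals[r] <- lg$value
      if (r == 1L) trace <- objs
    }
  })
  structure(list(pattern = acc / n_runs, class_index = class_index,
                 final_activation = mean(finals), activations = finals,
                 objective_trace = trace, n_runs = n_runs),
            class = "am_pattern")
}

#' Per-electrode energy of an AM pattern
#'
#' L2 norm over the frequency-by-time plane per electrode, min-max
#' normalized to `[0, 1]` (all-equal energies map to zeros).
#'
#' @param p an `am_pattern` (or a bare tensor channels x freq x time)
#' @param channel_names electrode labels of the channel axis
#' @return named numeric vector in `[0, 1]`
#' @export
channel_energy <- function(p, channel_names = NULL) {
  pat <- if (inherits(p, "am_pattern")) p$pattern else p
  e <- sqrt(apply(pat^2, 1L, sum))
  if (!is.null(channel_names)) names(e) <- channel_names
  normalize_scores(e)
}

#' Topographic map of per-electrode values
#'
#' Interpolates electrode values onto a 2-D head disc with Gaussian
#' radial basis functions over the azimuthal-equidistant electrode
#' positions, masked outside the head circle.
#'
#' @param values named numeric vector, electrode -> scalar; every name
#'   must exist in the montage
#' @param m a [montage]
#' @param grid_n grid resolution per axis
#' @param rbf_width kernel width in projected units
#' @return a `topo_map`: list with `grid` (`grid_n x grid_n` matrix, `NA`
#'   outside the head), `x`, `y` (grid axes), `electrodes` (tibble of
#'   positions and values)
#' @export
topoplot <- function(values, m = montage(STANDARD_21), grid_n = 64L,
                     rbf_width = 0.35) {
  unknown <- setdiff(names(values), m$names)
  if (length(unknown) > 0L)
    stop("unknown electrode(s): ", paste(unknown, collapse = ", "))
  pos <- m$positions_2d[names(values), , drop = FALSE]
  lim <- 1.25
  ax <- seq(-lim, lim, length.out = grid_n)
  gx <- matrix(ax, grid_n, grid_n)
  gy <- matrix(ax, grid_n, grid_n, byrow = TRUE)
  grid <- matrix(0, grid_n, grid_n)
  wsum <- matrix(0, grid_n, grid_n)
  for (i in seq_along(values)) {
    d2 <- (gx - pos[i, 1L])^2 + (gy - pos[i, 2L])^2
    w <- exp(-d2 / (2 * rbf_width^2))
    grid <- grid + w * values[i]
    wsum <- wsum + w
  }
  grid <- grid / pmax(wsum, 1e-12)
  grid[gx^2 + gy^2 > lim^2] <- NA
  structure(list(grid = grid, x = ax, y = ax,
                 electrodes = tibble::tibble(electrode = names(values),
                                             x = pos[, 1L], y = pos[, 2L],
                                             value = unname(values))),
            class = "topo_map")
}

#' @export
print.topo_map <- function(x, ...) {
  cat(sprintf("<topo_map> %d electrodes, %dx%d grid\n",
              nrow(x$electrodes), length(x$x), length(x$y)))
  invisible(x)
}

#' Render a topographic map
#'
#' @param object a `topo_map`
#' @param title optional plot title
#' @param ... ignored
#' @return a ggplot object
#' @export
autoplot.topo_map <- function(object, title = NULL, ...) {
  df <- expand.grid(x = object$x, y = object$y)
  df$value <- as.vector(object$grid)
  circ <- tibble::tibble(t = seq(0, 2 * pi, length.out = 200))
  ggplot2::ggplot() +
    ggplot2::geom_raster(data = df[!is.na(df$value), ],
                         ggplot2::aes(x = .data$x, y = .data$y,
                                      fill = .data$value)) +
    ggplot2::geom_path(data = tibble::tibble(x = cos(circ$t), y = sin(circ$t)),
                       ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(data = object$electrodes,
                        ggplot2::aes(x = .data$x, y = .data$y), size = 1) +
    ggplot2::geom_text(data = object$electrodes,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$electrode),
                       nudge_y = 0.08, size = 2.5) +
    ggplot2::scale_fill_viridis_c(limits = c(0, NA)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title, x = NULL, y = NULL, fill = "value") +
    ggplot2::theme_void()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
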