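#' Build a convolution/pooling layer stack description
#'
#' @param kernel Odd convolution kernel sizes (pixels), one per layer.
#' @param conv_stride Convolution strides (default 1 for all layers).
#' @param pool_kernel,pool_stride Max-pooling kernel/stride per layer; use
#'   `NA` where a layer has no pooling.
#' @return Tibble of class `layer_stack` with one row per layer.
#' @export
layer_stack <- function(kernel, conv_stride = rep(1L, length(kernel)),
                        pool_kernel = rep(NA_integer_, length(kernel)),
                        pool_stride = pool_kernel) {
  n <- length(kernel)
  if (any(kernel < 1) || any(kernel %% 2 == 0)) {
    abort("Kernels must be odd and >= 1.")
  }
  if (any(conv_stride < 1) || any(!is.na(pool_stride) & pool_stride < 1)) {
    abort("Strides must be >= 1 (zero stride is invalid).")
  }
  out <- tibble(
    layer = seq_len(n),
    kernel = as.integer(kernel),
    conv_stride = as.integer(conv_stride),
    pool_kernel = as.integer(pool_kernel),
    pool_stride = as.integer(pool_stride)
  )
  class(out) <- c("layer_stack", class(out))
  out
}

#' Effective receptive field of each layer in a stack
#'
#' Standard receptive-field recursion: starting from `rf = 1`, `jump = 1`,
#' each operation with kernel k and stride s updates
#' `rf <- rf + (k - 1) * jump` then `jump <- jump * s`. Convolution is
#' applied before the layer's pooling (if any), and the per-layer RF is read
#' after the layer's last operation. With `px_per_deg` the RF is also
#' expressed in degrees of visual angle.
#'
#' @param stack A [layer_stack()].
#' @param px_per_deg Optional pixels-per-degree scale (e.g.
#'   `input_px / fov_deg`) to convert RF to degrees.
#' @return The stack tibble with added columns `rf_px`, `jump`, and (when
#'   `px_per_deg` is given) `rf_deg`.
#' @examples
#' effective_rf(layer_stack(kernel = c(3, 3, 3)))
#' @export
effective_rf <- function(stack, px_per_deg = NULL) {
  rf <- 1
  jump <- 1
  rf_px <- integer(nrow(stack))
  jump_after <- integer(nrow(stack))
  for (i in seq_len(nrow(stack))) {
    rf <- rf + (stack$kernel[i] - 1) * jump
    jump <- jump * stack$conv_stride[i]
    if (!is.na(stack$pool_kernel[i])) {
      rf <- rf + (stack$pool_kernel[i] - 1) * jump
      jump <- jump * stack$pool_stride[i]
    }
    rf_px[i] <- rf
    jump_after[i] <- jump
  }
  out <- dplyr::mutate(stack, rf_px = rf_px, jump = jump_after)
  if (!is.null(px_per_deg)) {
    stopifnot_scalar_number(px_per_deg, "px_per_deg", lower = 1e-12)
    out$rf_deg <- out$rf_px / px_per_deg
  }
  out
}

#' Solve kernel sizes so layer receptive fields track cortical targets
#'
#' Chooses odd convolution kernels front to back so that each layer's
#' effective receptive field approximates a target RF (given in degrees of
#' visual angle, e.g. population-receptive-field sizes of successive ventral
#' stream areas at fixed eccentricity). The network's field of view maps the
#' input to degrees: `px_per_deg = input_px / fov_deg`. At each layer the
#' odd kernel minimising the absolute pixel error to the target — given the
#' kernels already fixed for earlier layers and the pooling layout — is
#' selected (ties to the smaller kernel). Targets that would need a kernel
#' below 1 are unreachable; the kernel is clamped to 1 with a warning.
#'
#' @param targets_deg Non-decreasing per-layer RF targets in degrees.
#' @param input_px Input image side length in pixels.
#' @param fov_deg Total field of view in degrees (default 3).
#' @param pool Logical per layer: is max pooling applied after the
#'   convolution? Defaults to [default_pool_layout()] when lengths match, else
#'   no pooling.
#' @param conv_stride Convolution strides (default all 1).
#' @param pool_kernel,pool_stride Pooling geometry where `pool` is `TRUE`
#'   (default 2/2).
#' @return A [layer_stack()] augmented by [effective_rf()] with columns
#'   `target_deg`, `target_px`, `rf_px`, `rf_deg`.
#' @export
solve_kernels <- function(targets_deg, input_px, fov_deg = 3.0,
                          pool = NULL, conv_stride = NULL,
                          pool_kernel = 2L, pool_stride = 2L) {
  n <- length(targets_deg)
  if (n < 1) abort("Need at least one target.")
  if (is.unsorted(targets_deg)) {
    abort("`targets_deg` must be non-decreasing (RF grows with depth).")
  }
  stopifnot_scalar_number(input_px, "input_px", lower = 1)
  stopifnot_scalar_number(fov_deg, "fov_deg", lower = 1e-12)
  px_per_deg <- input_px / fov_deg
  if (is.null(pool)) {
    pool <- if (n == 10) default_pool_layout() else rep(FALSE, n)
  }
  if (is.null(conv_stride)) conv_stride <- rep(1L, n)
  if (length(pool) != n || length(conv_stride) != n) {
    abort("`pool` and `conv_stride` must have one entry per layer.")
  }
  targets_px <- targets_deg * px_per_deg

  kernels <- integer(n)
  rf <- 1
  jump <- 1
  clamped <- FALSE
  for (i in seq_len(n)) {
    pk <- if (pool[i]) pool_kernel else 0L
    ps <- if (pool[i]) pool_stride else 1L
    # rf after layer i as a function of kernel k:
    #   rf + (k - 1) * jump + (pk - 1) * jump * conv_stride   (pk > 0)
    pool_add <- if (pool[i]) (pk - 1) * jump * conv_stride[i] else 0
    ideal <- (targets_px[i] - rf - pool_add) / jump + 1
    cand <- unique(pmax(1, c(2 * floor((ideal - 1) / 2) + 1,
                             2 * ceiling((ideal - 1) / 2) + 1)))
    achieved <- rf + (cand - 1) * jump + pool_add
    err <- abs(achieved - targets_px[i])
    k <- cand[order(err, cand)][1]
    if (ideal < 1) clamped <- TRUE
    kernels[i] <- k
    rf <- rf + (k - 1) * jump + pool_add
    jump <- jump * conv_stride[i] * ps
  }
  if (clamped) {
    warn("Some targets unreachable; kernel clamped to 1 for those layers.")
  }
  stack <- layer_stack(
    kernel = kernels, conv_stride = conv_stride,
    pool_kernel = ifelse(pool, pool_kernel, NA_integer_),
    pool_stride = ifelse(pool, pool_stride, NA_integer_)
  )
  out <- effective_rf(stack, px_per_deg = px_per_deg)
  out$target_deg <- targets_deg
  out$target_px <- targets_px
  out
}

#' Default pooling layout for the 10-layer ventral-stream-inspired network
#'
#' Max pooling is disabled in layers 1, 2, 5 and 6 (and there is no pooling
#' before layer 1); all other layers pool.
#'
#' @return Logical vector of length 10.
#' @export
default_pool_layout <- function() {
  !(seq_len(10L) %in% c(1L, 2L, 5L, 6L))
}

#' Placeholder receptive-field target progression
#'
#' The cortical pRF sizes the architecture tracks (V1, V2, V3, hV4, LO, TO,
#' pFUS, mFUS at 0.75 deg eccentricity, plus two extrapolated anterior
#' stages) are estimates external to this package; published values are
#' required user input. This documented placeholder provides a smoothly
#' increasing progression in degrees for tests and examples only.
#'
#' @return Numeric vector of 10 RF targets in degrees.
#' @export
placeholder_rf_targets <- function() {
  c(0.3, 0.45, 0.65, 0.9, 1.2, 1.55, 2.0, 2.5, 3.1, 3.8)
}

#' Emit an architecture description as JSON
#'
#' Serialises a solved layer stack together with the visual-field mapping
#' and (optionally) training hyperparameters recorded for provenance only —
#' nothing in this package trains a network.
#'
#' @param stack Output of [solve_kernels()] or [effective_rf()].
#' @param path Output path.
#' @param input_px,fov_deg Visual field mapping to record.
#' @param eccentricity_deg Eccentricity (degrees) at which the target pRF
#'   sizes were estimated; metadata only (default 0.75).
#' @param hyperparameters Optional named list recorded verbatim.
#' @return `path`, invisibly.
#' @export
write_architecture_json <- function(stack, path, input_px = NULL,
                                    fov_deg = NULL,
                                    eccentricity_deg = 0.75,
                                    hyperparameters = NULL) {
  jsonlite::write_json(
    list(field_of_view = list(input_px = input_px, fov_deg = fov_deg,
                              eccentricity_deg = eccentricity_deg),
         layers = as.data.frame(stack),
         hyperparameters = hyperparameters),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
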