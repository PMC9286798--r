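#' Standard 64-channel 10-10 montage
#'
#' Returns the 64 scalp electrode labels of the Biosemi 10-10 layout together
#' with 2-D positions from an azimuthal-equidistant projection of the standard
#' spherical electrode coordinates (head radius in radians of inclination;
#' vertex Cz at the origin, nose towards positive y).
#'
#' @return A tibble with columns `label`, `x`, `y` (64 rows).
#' @export
#' @examples
#' mid_montage()
mid_montage <- function() {
  path <- system.file("extdata", "biosemi64_positions.tsv",
                      package = "middecode", mustWork = TRUE)
  as_tibble(read.delim(path, stringsAsFactors = FALSE))
}

#' Smooth scalp topography centred on an electrode site
#'
#' Builds a unit-norm channel weight vector as a spatial Gaussian over the 2-D
#' montage positions, peaked at `center` (an electrode label). Used by the
#' simulator to plant components with, e.g., a parietal or fronto-central
#' distribution, and convenient for comparing recovered forward models against
#' planted patterns.
#'
#' @param center Electrode label at the peak (e.g. `"Pz"`, `"FCz"`).
#' @param width Spatial standard deviation of the Gaussian, in montage
#'   projection units (the whole scalp spans roughly 4 units); default 0.6.
#' @param montage Montage tibble as returned by [mid_montage()].
#' @return Named numeric vector (one weight per channel) with unit L2 norm.
#' @export
#' @examples
#' w <- scalp_topography("Pz")
#' sum(w^2)
scalp_topography <- function(center, width = 0.6, montage = mid_montage()) {
  assert_that(center %in% montage$label,
              sprintf("unknown electrode label '%s'", center))
  p0 <- montage[montage$label == center, c("x", "y")]
  d2 <- (montage$x - p0$x)^2 + (montage$y - p0$y)^2
  w <- exp(-d2 / (2 * width^2))
  w <- w / sqrt(sum(w^2))
  stats::setNames(w, montage$label)
}

# Spatial correlation matrix for simulated sensor noise: squared-exponential
# over montage distance plus a nugget, guaranteeing positive definiteness.
spatial_noise_cov <- function(montage, length_scale = 0.8, nugget = 0.1) {
  d2 <- outer(montage$x, montage$x, "-")^2 + outer(montage$y, montage$y, "-")^2
  k <- (1 - nugget) * exp(-d2 / (2 * length_scale^2))
  diag(k) <- 1
  k
}

#' Plot channel values on the scalp
#'
#' Simple 2-D scalp map: one point per electrode at its montage position,
#' coloured by `values`. Intended for quick inspection of forward models and
#' difference-wave topographies; no interpolation is performed.
#'
#' @param values Named numeric vector (names = electrode labels) or unnamed
#'   vector in montage order.
#' @param montage Montage tibble, see [mid_montage()].
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_topography <- function(values, montage = mid_montage(), title = NULL) {
  if (!is.null(names(values))) {
    idx <- match(montage$label, names(values))
    assert_that(!anyNA(idx), "values must be named by montage electrode labels")
    values <- values[idx]
  }
  assert_that(length(values) == nrow(montage),
              "length(values) must equal the number of montage channels")
  df <- dplyr::mutate(montage, value = as.numeric(values))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$value), size = 6) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 2,
                       vjust = -1.6) +
    ggplot2::scale_colour_gradient2(low = "#2166AC", mid = "white",
                                    high = "#B2182B") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = title, colour = "a.u.") +
    ggplot2::theme_void()
}
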