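# Volume -> mass conversion at standard tissue densities, and the two
# normalisations used when comparing mass estimates across methods.

#' Tissue density parameters
#'
#' Defaults are the standard literature densities: 1060 kg/m^3 for muscle
#' tissue and 1120 kg/m^3 (about 5% higher) for tendon.
#'
#' @param muscle_density Muscle density in kg/m^3.
#' @param tendon_density Tendon density in kg/m^3.
#' @return A named list of class `mass_params`.
#' @export
mass_params <- function(muscle_density = 1060, tendon_density = 1120) {
  if (muscle_density <= 0 || tendon_density <= 0) {
    stop("densities must be positive", call. = FALSE)
  }
  structure(
    list(muscle_density = muscle_density, tendon_density = tendon_density),
    class = "mass_params"
  )
}

#' Muscle mass from volume
#'
#' Converts a volume in the given unit to cubic metres and multiplies by a
#' homogeneous muscle density (default 1060 kg/m^3).
#'
#' @param volume Volume (scalar or vector), non-negative.
#' @param unit Volume unit: `"mm"`, `"cm"` or `"m"` (interpreted cubed).
#' @param params A [mass_params()].
#' @return Mass in kg.
#' @export
mass_from_volume <- function(volume, unit = "cm", params = mass_params()) {
  if (any(volume < 0)) stop("volume must be >= 0", call. = FALSE)
  volume * unit_volume_factor(unit) * params$muscle_density
}

#' Mass of a muscle-tendon composite
#'
#' Muscle and tendon volumes convert at their respective densities and sum.
#' With `tendon_volume = 0` this reduces to [mass_from_volume()].
#'
#' @param muscle_volume,tendon_volume Volumes, non-negative.
#' @param unit Volume unit (cubed).
#' @param params A [mass_params()].
#' @return Mass in kg.
#' @export
composite_mass <- function(muscle_volume, tendon_volume = 0, unit = "cm",
                           params = mass_params()) {
  if (any(muscle_volume < 0) || any(tendon_volume < 0)) {
    stop("volumes must be >= 0", call. = FALSE)
  }
  fac <- unit_volume_factor(unit)
  muscle_volume * fac * params$muscle_density +
    tendon_volume * fac * params$tendon_density
}

#' Normalise muscle mass by body mass
#'
#' @param data A data frame with a `mass` column (kg).
#' @param body_mass Body mass in kg (> 0).
#' @return The data as a tibble with a `normalized_mass` column
#'   (dimensionless muscle mass / body mass).
#' @export
normalize_by_body_mass <- function(data, body_mass) {
  if (body_mass <= 0) stop("body_mass must be > 0", call. = FALSE)
  dplyr::mutate(tibble::as_tibble(data),
    body_mass = body_mass,
    normalized_mass = .data$mass / body_mass
  )
}

#' Normalise a value by the median of reference measurements
#'
#' @param value Numeric value(s), e.g. a modelled muscle mass.
#' @param reference Non-empty numeric vector of reference measurements for
#'   the same muscle; for an even number of values the median is the mean of
#'   the two middle order statistics.
#' @return `value / median(reference)`.
#' @export
normalize_by_reference_median <- function(value, reference) {
  if (length(reference) == 0) stop("reference is empty", call. = FALSE)
  m <- median(reference)
  if (m == 0) stop("reference median is zero", call. = FALSE)
  value / m
}

#' Muscle mass table from volumes
#'
#' Tabular front end over [mass_from_volume()]: takes one row per muscle
#' with a volume column and appends mass (kg) and, if a body mass is given,
#' normalised mass. Report-style rounding to 3 decimals (kg) is optional.
#'
#' @param data Data frame with columns `muscle` and `volume`.
#' @param unit Volume unit (cubed).
#' @param params A [mass_params()].
#' @param body_mass Optional body mass in kg.
#' @param round_kg Round the mass column to 3 decimals (table presentation).
#' @return A tibble with `muscle`, `volume`, `mass` and optionally
#'   `normalized_mass`.
#' @export
muscle_mass_table <- function(data, unit = "cm", params = mass_params(),
                              body_mass = NULL, round_kg = FALSE) {
  out <- tibble::as_tibble(data) |>
    dplyr::mutate(mass = mass_from_volume(.data$volume, unit, params))
  if (round_kg) out <- dplyr::mutate(out, mass = round(.data$mass, 3))
  if (!is.null(body_mass)) out <- normalize_by_body_mass(out, body_mass)
  out
}

#' Gorilla shoulder muscle comparison table
#'
#' Published comparison between dissection-measured masses and masses
#' calculated from volumetric polygonal muscle models for five shoulder
#' muscles of a western lowland gorilla (plus the combined deltoid and the
#' total): measured mass (kg), modelled volume (cm^3) and LoA arc length
#' (cm, where defined). Shipped as plain CSV in `inst/extdata`.
#'
#' @return A tibble with columns `muscle`, `measured_mass_kg`,
#'   `modelled_volume_cm3`, `loa_length_cm` and `is_aggregate` (flags the
#'   combined-deltoid and total rows).
#' @export
gorilla_shoulder_muscles <- function() {
  path <- system.file("extdata", "gorilla_shoulder_muscles.csv",
    package = "myoline", mustWork = TRUE
  )
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE)) |>
    dplyr::mutate(is_aggregate = as.logical(.data$is_aggregate))
}
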