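#' Zone classes
#'
#' The four classes of physical location used throughout the package. The
#' first three (patient rooms, nursing stations, service areas) are the main
#' work areas; `off_main` is the uninstrumented complement (halls, break and
#' locker rooms).
#' @export
zone_classes <- c("patient_room", "nursing_station", "service_area", "off_main")

#' Main work area classes
#' @export
main_zone_classes <- zone_classes[1:3]

#' Construct a unit map
#'
#' A unit map lists the physical zones of the nursing unit, the class of each
#' zone, and how many stationary sensor badges it holds. Ambient channels
#' (noise, temperature) are only observed in zones with at least one sensor.
#'
#' @param zones A data frame with columns `zone_id`, `zone_class` and
#'   `n_sensors`.
#' @return A tibble of class `unit_map`.
#' @export
unit_map <- function(zones) {
  zones <- tibble::as_tibble(zones)
  required <- c("zone_id", "zone_class", "n_sensors")
  missing <- setdiff(required, names(zones))
  if (length(missing)) {
    stop("unit map is missing columns: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(zones$zone_id)) stop("zone_ids must be unique")
  bad <- setdiff(unique(zones$zone_class), zone_classes)
  if (length(bad)) stop("unknown zone classes: ", paste(bad, collapse = ", "))
  absent <- setdiff(zone_classes, zones$zone_class)
  if (length(absent)) {
    stop("unit map must contain at least one zone of each class; missing: ",
         paste(absent, collapse = ", "))
  }
  if (any(zones$n_sensors < 0)) stop("n_sensors must be non-negative")
  class(zones) <- c("unit_map", class(zones))
  zones
}

#' Default surgical ICU unit map
#'
#' Sixteen instrumented patient rooms (two badges each), two nursing stations
#' (three badges each), three service areas (medication, supply, nutrition;
#' one badge each), and a single pseudo-zone collecting all locations outside
#' the main work areas (no sensors).
#'
#' @return A `unit_map`.
#' @export
default_unit_map <- function() {
  unit_map(tibble::tibble(
    zone_id = c(sprintf("pr%02d", 1:16), "ns1", "ns2",
                "sa_medication", "sa_supply", "sa_nutrition", "off_main"),
    zone_class = c(rep("patient_room", 16), rep("nursing_station", 2),
                   rep("service_area", 3), "off_main"),
    n_sensors = c(rep(2L, 16), rep(3L, 2), rep(1L, 3), 0L)
  ))
}

zone_class_of <- function(map) {
  setNames(map$zone_class, map$zone_id)
}
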