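#' Total delta-V from lateral and longitudinal components
#'
#' Combines the lateral (side-to-side) and longitudinal (front-to-back)
#' velocity-change components into a total delta-V by the Euclidean norm,
#' the standard vector interpretation of component-wise speed change.
#'
#' @param lateral_dv,longitudinal_dv non-negative component magnitudes, km/h.
#'   Vectorised.
#' @return Total delta-V in km/h.
#' @examples
#' total_delta_v(3, 4)  # 5
#' @export
total_delta_v <- function(lateral_dv, longitudinal_dv) {
  if (any(lateral_dv < 0, na.rm = TRUE) || any(longitudinal_dv < 0, na.rm = TRUE))
    stop("delta-V components must be non-negative")
  sqrt(lateral_dv^2 + longitudinal_dv^2)
}

#' Dominant delta-V component
#'
#' Flags whichever component has the strictly larger magnitude. Exact ties
#' are labelled `"tie"`; tie records are excluded from dominance analyses
#' downstream because they support neither direction.
#'
#' @inheritParams total_delta_v
#' @return Character vector in `{"lateral", "longitudinal", "tie"}` (`NA`
#'   where either component is missing).
#' @export
dominant_component <- function(lateral_dv, longitudinal_dv) {
  if (any(lateral_dv < 0, na.rm = TRUE) || any(longitudinal_dv < 0, na.rm = TRUE))
    stop("delta-V components must be non-negative")
  out <- ifelse(lateral_dv > longitudinal_dv, "lateral",
                ifelse(longitudinal_dv > lateral_dv, "longitudinal", "tie"))
  out[is.na(lateral_dv) | is.na(longitudinal_dv)] <- NA_character_
  out
}

#' Delta-V for vulnerable road users
#'
#' A struck pedestrian or cyclist is accelerated up to the speed of the
#' impacting vehicle, so pedestrian delta-V is approximated by the vehicle
#' impact speed. Cyclists travel at meaningful speeds along the carriageway,
#' so the component of cyclist velocity parallel to the vehicle's travel is
#' combined with the vehicle impact speed. `vru_parallel_fraction` is the
#' signed cosine of the angle between the two travel directions: positive
#' values oppose the vehicle (head-on, adds speed), negative values are
#' same-direction travel (subtracts); the result is floored at zero.
#'
#' @param road_user `"pedestrian"` or `"cyclist"`; the method is undefined
#'   for other road users.
#' @param vehicle_impact_speed striking vehicle speed at impact, km/h.
#' @param vru_speed VRU travel speed, km/h (ignored for pedestrians).
#' @param vru_parallel_fraction signed fraction in `[-1, 1]`.
#' @return VRU delta-V in km/h. Vectorised over speeds.
#' @examples
#' vru_delta_v("pedestrian", 32)                 # 32
#' vru_delta_v("cyclist", 30, 20, 0)             # perpendicular crossing: 30
#' vru_delta_v("cyclist", 30, 20, 1)             # head-on: 50
#' @export
vru_delta_v <- function(road_user, vehicle_impact_speed, vru_speed = 0,
                        vru_parallel_fraction = 0) {
  if (!all(road_user %in% c("pedestrian", "cyclist")))
    stop("VRU delta-V is defined only for pedestrians and cyclists")
  if (any(vehicle_impact_speed < 0, na.rm = TRUE) || any(vru_speed < 0, na.rm = TRUE))
    stop("speeds must be non-negative")
  if (any(abs(vru_parallel_fraction) > 1, na.rm = TRUE))
    stop("vru_parallel_fraction must lie in [-1, 1]")
  n <- max(length(road_user), length(vehicle_impact_speed),
           length(vru_speed), length(vru_parallel_fraction))
  road_user <- rep_len(road_user, n)
  vehicle_impact_speed <- rep_len(vehicle_impact_speed, n)
  vru_speed <- rep_len(vru_speed, n)
  vru_parallel_fraction <- rep_len(vru_parallel_fraction, n)
  out <- ifelse(road_user == "pedestrian",
                vehicle_impact_speed,
                pmax(0, vehicle_impact_speed + vru_parallel_fraction * vru_speed))
  unname(out)
}

#' Study eligibility of a subject's collision dynamics
#'
#' Applies the inclusion rules for dynamics-based analyses: VRUs directly
#' run over are excluded (the acceleration-to-vehicle-speed assumption does
#' not hold); multi-impact collisions are included only when one impact
#' phase is clearly injury-causing; and records missing the dynamics fields
#' required for their road-user type are excluded.
#'
#' @param records data frame with columns `road_user`, `runover`,
#'   `impact_count`, `injury_causing_phase_known`, and the dynamics fields
#'   (`total_dv` or both components for vehicle occupants;
#'   `vehicle_impact_speed` for pedestrians/cyclists).
#' @return Data frame with `include` (logical) and `reason` (one of `"ok"`,
#'   `"runover"`, `"multi_impact_unclear"`, `"missing_dynamics"`), one row
#'   per input record.
#' @export
eligibility <- function(records) {
  n <- nrow(records)
  col <- function(name, default) {
    if (name %in% names(records)) records[[name]] else rep(default, n)
  }
  runover <- col("runover", FALSE)
  impact_count <- col("impact_count", 1L)
  phase_known <- col("injury_causing_phase_known", TRUE)
  road_user <- col("road_user", "car_occupant")
  total_dv <- col("total_dv", NA_real_)
  lat <- col("lateral_dv", NA_real_)
  lon <- col("longitudinal_dv", NA_real_)
  impact_speed <- col("vehicle_impact_speed", NA_real_)

  is_vru_struck <- road_user %in% c("pedestrian", "cyclist")
  has_dyn <- ifelse(is_vru_struck,
                    !is.na(impact_speed),
                    !is.na(total_dv) | (!is.na(lat) & !is.na(lon)))
  reason <- rep("ok", n)
  reason[!has_dyn] <- "missing_dynamics"
  reason[impact_count > 1 & !isTRUE_vec(phase_known)] <- "multi_impact_unclear"
  reason[isTRUE_vec(runover)] <- "runover"
  data.frame(include = reason == "ok", reason = reason,
             stringsAsFactors = FALSE)
}

isTRUE_vec <- function(x) !is.na(x) & x
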