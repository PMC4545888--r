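LIP_LOCATIONS <- c("L1", "L2", "L3", "R1", "R2", "R3")
ORIENTATIONS <- c("E_left", "E_right")

# positions allowed per set size: top row only for 2, top+middle for 4
positions_for_set_size <- function(set_size) {
  switch(as.character(set_size),
    "2" = c("L1", "R1"),
    "4" = c("L1", "R1", "L2", "R2"),
    "6" = LIP_LOCATIONS,
    stop("set_size must be 2, 4 or 6", call. = FALSE)
  )
}

#' Trial conditions for the covert search task
#'
#' A condition is the stimulus triplet (set size, target position, target
#' orientation). Positions are labelled `L1..L3` (left hemifield, top to
#' bottom) and `R1..R3` (right hemifield); orientations are `E_left`
#' (left-facing, correct response = left bar release) and `E_right`
#' (right-facing, correct response = right). A trial is response-hemifield
#' *congruent* when the required release is on the same side as the target:
#' a right-facing target in the right hemifield or a left-facing target in
#' the left hemifield.
#'
#' @param set_size number of stimuli on screen: 2, 4 or 6.
#' @param position target location label; must be a stimulated location for
#'   the given set size (`L1`/`R1` for set size 2; additionally `L2`/`R2`
#'   for set size 4; any location for set size 6).
#' @param orientation `"E_left"` or `"E_right"`.
#' @return a one-row tibble with columns `set_size`, `position`,
#'   `orientation`, `congruent`.
#' @export
#' @examples
#' trial_condition(4, "R1", "E_right") # congruent
#' trial_condition(4, "L1", "E_right") # incongruent
trial_condition <- function(set_size, position, orientation) {
  set_size <- as.integer(set_size)
  if (!set_size %in% c(2L, 4L, 6L)) {
    stop("set_size must be 2, 4 or 6", call. = FALSE)
  }
  position <- match.arg(position, LIP_LOCATIONS)
  orientation <- match.arg(orientation, ORIENTATIONS)
  if (!position %in% positions_for_set_size(set_size)) {
    stop("position ", position, " is not stimulated at set size ", set_size,
      call. = FALSE
    )
  }
  tibble(
    set_size = set_size, position = position, orientation = orientation,
    congruent = is_congruent(position, orientation)
  )
}

#' Classify response-hemifield congruence
#'
#' Congruent trials have right-facing targets in the right hemifield or
#' left-facing targets in the left hemifield, so the correct bar release is
#' on the same side of the display as the target.
#'
#' @param position target location label (`L1..L3`, `R1..R3`), vectorised.
#' @param orientation `"E_left"` or `"E_right"`, vectorised.
#' @return logical vector.
#' @export
is_congruent <- function(position, orientation) {
  stopifnot(all(position %in% LIP_LOCATIONS), all(orientation %in% ORIENTATIONS))
  side <- ifelse(substr(position, 1, 1) == "R", "R", "L")
  resp <- ifelse(orientation == "E_right", "R", "L")
  side == resp
}

#' Ring topology of the six LIP units
#'
#' The six LIP units tile the stimulus ring in the cycle
#' L1 - R1 - R2 - R3 - L3 - L2 - L1. Mutual inhibition decays with ring
#' distance: full strength `eta_lip` at distance 1, `eta_lip * decay1` at
#' distance 2 and `eta_lip * decay1 * decay2` at distance 3 (the antipodal
#' unit).
#'
#' @return a tibble with columns `from`, `to`, `distance` (1, 2 or 3) for
#'   all ordered pairs of distinct units.
#' @export
#' @examples
#' lip_topology() %>% dplyr::filter(from == "L1")
lip_topology <- function() {
  cycle <- c("L1", "R1", "R2", "R3", "L3", "L2")
  pos <- setNames(seq_along(cycle) - 1L, cycle)
  grid <- expand.grid(
    from = LIP_LOCATIONS, to = LIP_LOCATIONS,
    stringsAsFactors = FALSE
  )
  grid <- grid[grid$from != grid$to, ]
  d <- abs(pos[grid$from] - pos[grid$to])
  grid$distance <- as.integer(pmin(d, 6L - d))
  as_tibble(grid[order(grid$from, grid$distance, grid$to), ])
}

#' Stimulus input schedules
#'
#' `perceptual_input()` gives the mean perceptual drive reaching a LIP
#' location after the perceptual delay: locations `L1`/`R1` are stimulated
#' at set size 2, `L1`/`R1`/`L2`/`R2` at set size 4 and all six at set
#' size 6. `target_input()` gives the additional target drive, which reaches
#' only the target's own location after the further search delay.
#' `orientation_input()` gives the drive to an IT orientation unit: `s_ori`
#' on the unit matching the target orientation, 0 on the other.
#'
#' @param set_size 2, 4 or 6.
#' @param location a LIP location label.
#' @param s_lip,s_tar,s_ori input strengths (default 1 gives an indicator).
#' @param position target location label.
#' @param orientation,it_unit orientation labels (`"E_left"`/`"E_right"`).
#' @return input strength (numeric scalar).
#' @export
perceptual_input <- function(set_size, location, s_lip = 1) {
  location <- match.arg(location, LIP_LOCATIONS)
  if (location %in% positions_for_set_size(set_size)) s_lip else 0
}

#' @rdname perceptual_input
#' @export
target_input <- function(position, location, s_tar = 1) {
  position <- match.arg(position, LIP_LOCATIONS)
  location <- match.arg(location, LIP_LOCATIONS)
  if (position == location) s_tar else 0
}

#' @rdname perceptual_input
#' @export
orientation_input <- function(orientation, it_unit, s_ori = 1) {
  orientation <- match.arg(orientation, ORIENTATIONS)
  it_unit <- match.arg(it_unit, ORIENTATIONS)
  if (orientation == it_unit) s_ori else 0
}

# integer codes used by the C++ engine
condition_codes <- function(condition) {
  stopifnot(is.data.frame(condition), nrow(condition) == 1L)
  list(
    set_size = as.integer(condition$set_size),
    pos = match(condition$position, LIP_LOCATIONS) - 1L,
    ori = match(condition$orientation, ORIENTATIONS) - 1L
  )
}

# mirror a condition across the vertical midline
mirror_condition <- function(condition) {
  swap <- function(x) chartr("LR", "RL", x)
  tibble(
    set_size = condition$set_size,
    position = swap(condition$position),
    orientation = ifelse(condition$orientation == "E_left", "E_right", "E_left"),
    congruent = condition$congruent
  )
}
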