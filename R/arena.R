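#' Arena geometries
#'
#' Two arena variants are used by the assays: the rectangular social
#' preference chamber (a test area flanked by two stimulus areas behind
#' transparent walls) and the circular shoaling arena.
#'
#' Coordinates are in mm. The origin sits at the lower-left corner of the
#' test area (rectangular chamber) or of the bounding square of the circular
#' arena; x increases rightward, y upward. For the rectangular chamber the
#' stimulus areas lie outside the `[0, test_width]` x-range, on the side named
#' by `stimulus_side`.
#'
#' The chamber defaults match the assay sizes used for 2-4 week-old fish
#' (test area 25 x 75 mm, stimulus areas 8 x 75 mm); 8-week-old fish use a
#' 50 x 75 mm test area with 16 x 75 mm stimulus areas. The circular arena
#' defaults to 700 mm diameter.
#'
#' @param test_width_mm,test_length_mm test-area width (the axis split by the
#'   social/antisocial midline) and length, mm.
#' @param stim_width_mm,stim_length_mm stimulus-area width and length, mm.
#' @param stimulus_side which stimulus area is occupied: `"left"` (at x < 0)
#'   or `"right"` (at x > test_width).
#' @param diameter_mm circular arena diameter, mm.
#' @return An `ArenaGeometry` object (a list with a `variant` field).
#' @examples
#' rectangular_chamber()                      # 2-4 wpf chamber, stimulus left
#' rectangular_chamber(50, 75, 16, 75, "right")  # 8 wpf chamber
#' circular_arena()                           # 70 cm shoaling arena
#' @export
rectangular_chamber <- function(test_width_mm = 25, test_length_mm = 75,
                                stim_width_mm = 8, stim_length_mm = 75,
                                stimulus_side = c("left", "right")) {
  stimulus_side <- match.arg(stimulus_side)
  dims <- c(test_width_mm, test_length_mm, stim_width_mm, stim_length_mm)
  if (!all(is.finite(dims)) || any(dims <= 0)) {
    stopf("all chamber dimensions must be positive and finite")
  }
  structure(
    list(
      variant = "rectangular-chamber",
      test_width_mm = test_width_mm,
      test_length_mm = test_length_mm,
      stim_width_mm = stim_width_mm,
      stim_length_mm = stim_length_mm,
      stimulus_side = stimulus_side
    ),
    class = "ArenaGeometry"
  )
}

#' @rdname rectangular_chamber
#' @export
circular_arena <- function(diameter_mm = 700) {
  if (!is.finite(diameter_mm) || diameter_mm <= 0) {
    stopf("arena diameter must be positive and finite")
  }
  structure(
    list(variant = "circular-arena", diameter_mm = diameter_mm),
    class = "ArenaGeometry"
  )
}

is_rectangular <- function(arena) {
  inherits(arena, "ArenaGeometry") && arena$variant == "rectangular-chamber"
}

is_circular <- function(arena) {
  inherits(arena, "ArenaGeometry") && arena$variant == "circular-arena"
}

# Bounding region in which (test-fish) positions are expected to lie.
arena_bounds <- function(arena) {
  stopifnot(inherits(arena, "ArenaGeometry"))
  if (is_rectangular(arena)) {
    list(xlim = c(0, arena$test_width_mm), ylim = c(0, arena$test_length_mm))
  } else {
    list(xlim = c(0, arena$diameter_mm), ylim = c(0, arena$diameter_mm))
  }
}

arena_center <- function(arena) {
  b <- arena_bounds(arena)
  c(mean(b$xlim), mean(b$ylim))
}

#' @export
print.ArenaGeometry <- function(x, ...) {
  if (is_rectangular(x)) {
    cat(sprintf(
      "<ArenaGeometry> rectangular chamber: test %g x %g mm, stimulus %g x %g mm (%s)\n",
      x$test_width_mm, x$test_length_mm, x$stim_width_mm, x$stim_length_mm,
      x$stimulus_side
    ))
  } else {
    cat(sprintf("<ArenaGeometry> circular arena: diameter %g mm\n", x$diameter_mm))
  }
  invisible(x)
}

arena_to_list <- function(arena) {
  unclass(arena)
}

arena_from_list <- function(x) {
  if (is.null(x$variant)) stopf("arena metadata lacks a 'variant' field")
  if (x$variant == "rectangular-chamber") {
    rectangular_chamber(
      test_width_mm = x$test_width_mm, test_length_mm = x$test_length_mm,
      stim_width_mm = x$stim_width_mm, stim_length_mm = x$stim_length_mm,
      stimulus_side = x$stimulus_side
    )
  } else if (x$variant == "circular-arena") {
    circular_arena(diameter_mm = x$diameter_mm)
  } else {
    stopf("unknown arena variant '%s'", x$variant)
  }
}
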