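#' Load a body-segment inertial parameter (BSIP) table
#'
#' Reads one of the bundled anthropometric tables, or a user-supplied file in
#' the same format.  A BSIP table has one row per rigid segment and columns
#' `name`, `side` (`left`/`right`/`none`), `group` (limb group),
#' `proximal_marker`, `distal_marker`, `mass_fraction` (of total body mass),
#' `com_fraction` (segment centre of mass as a fraction of segment length from
#' the proximal end) and `gyration_fraction` (radius of gyration about the
#' segment centre of mass as a fraction of segment length).
#'
#' Two tables are bundled: `"winter"` (Dempster-derived fractions, the
#' default) and `"deleva"` (adjusted from de Leva's adult male values).  In
#' both, the hand is merged into the forearm and the head into the trunk, so
#' that the 11 segments (head-trunk, two upper arms, two forearms, two
#' thighs, two shanks, two feet) are defined by nine sagittal markers per
#' side plus shared head and hip markers.
#'
#' @param source `"winter"` or `"deleva"`; ignored when `path` is given.
#' @param path Optional path to a tab-separated BSIP file with the columns
#'   described above.
#' @return A `data.frame` with one row per segment.
#' @export
bsip_table <- function(source = c("winter", "deleva"), path = NULL) {
  if (is.null(path)) {
    source <- match.arg(source)
    path <- system.file("extdata", paste0("bsip_", source, ".tsv"),
                        package = "mechwork", mustWork = TRUE)
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("name", "side", "group", "proximal_marker", "distal_marker",
                "mass_fraction", "com_fraction", "gyration_fraction")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0)
    stop("BSIP table is missing columns: ", paste(missing, collapse = ", "))
  if (any(tab$mass_fraction <= 0 | tab$mass_fraction >= 1))
    stop("mass_fraction values must lie strictly between 0 and 1")
  if (any(tab$com_fraction < 0 | tab$com_fraction > 1))
    stop("com_fraction values must lie in [0, 1]")
  if (any(tab$gyration_fraction < 0 | tab$gyration_fraction > 1))
    stop("gyration_fraction values must lie in [0, 1]")
  if (anyDuplicated(tab$name))
    stop("duplicated segment names in BSIP table")
  tab
}

#' Build an 11-segment anthropometric body model
#'
#' Constructs the rigid-segment model used by all kinematic and energetic
#' computations: 11 segments (head-trunk, upper arms, forearms, thighs,
#' shanks, feet) partitioned into five limb groups (left/right upper limb,
#' left/right lower limb, head-trunk).  Segment masses are
#' `mass_fraction * total_mass`; mass fractions are renormalised at
#' construction so they sum exactly to one.
#'
#' @param total_mass Body mass in kg (`M`).
#' @param body_height Stature in m.
#' @param bsip A BSIP table as returned by [bsip_table()].
#' @param g Gravitational acceleration in m s^-2 (default 9.81).
#' @return An object of class `body_model`: a list with elements `segments`
#'   (the renormalised BSIP table), `total_mass`, `body_height` and `g`.
#' @examples
#' m <- build_body_model(70, 1.71)
#' segment_mass(m, "thigh_L")
#' @export
build_body_model <- function(total_mass, body_height,
                             bsip = bsip_table("winter"), g = 9.81) {
  if (!is.numeric(total_mass) || length(total_mass) != 1 || total_mass <= 0)
    stop("total_mass must be a single positive number (kg)")
  if (!is.numeric(body_height) || length(body_height) != 1 || body_height <= 0)
    stop("body_height must be a single positive number (m)")
  if (nrow(bsip) != 11)
    stop("expected 11 segments in the BSIP table, got ", nrow(bsip))
  bsip$mass_fraction <- bsip$mass_fraction / sum(bsip$mass_fraction)
  structure(
    list(segments = bsip, total_mass = total_mass,
         body_height = body_height, g = g),
    class = "body_model")
}

#' Segment mass in kilograms
#'
#' @param model A [build_body_model()] object.
#' @param name Segment name, e.g. `"thigh_L"`.
#' @return `mass_fraction * total_mass`, in kg.
#' @export
segment_mass <- function(model, name) {
  stopifnot(inherits(model, "body_model"))
  i <- match(name, model$segments$name)
  if (anyNA(i))
    stop("unknown segment name(s): ",
         paste(name[is.na(i)], collapse = ", "))
  model$segments$mass_fraction[i] * model$total_mass
}

#' Limb groups of a body model
#'
#' @param model A [build_body_model()] object.
#' @return A named list mapping each of the five limb groups to the segment
#'   names it contains.
#' @export
limb_groups <- function(model) {
  stopifnot(inherits(model, "body_model"))
  split(model$segments$name, model$segments$group)
}

#' Marker names required by a body model
#'
#' @param model A [build_body_model()] object.
#' @param sides Which sides to include; right-side markers can be synthesised
#'   from the left by [mirror_contralateral()].
#' @return Character vector of marker labels.
#' @export
model_markers <- function(model, sides = c("L", "R")) {
  segs <- model$segments
  mk <- unique(c(segs$proximal_marker, segs$distal_marker))
  keep <- !grepl("_[LR]$", mk)
  for (s in sides) keep <- keep | grepl(paste0("_", s, "$"), mk)
  mk[keep]
}

#' @export
print.body_model <- function(x, ...) {
  cat(sprintf("Body model: %d segments, %d limb groups\n",
              nrow(x$segments), length(unique(x$segments$group))))
  cat(sprintf("  total mass %.1f kg, height %.2f m, g = %.2f m s^-2\n",
              x$total_mass, x$body_height, x$g))
  invisible(x)
}
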