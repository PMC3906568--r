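#' Rig configuration and the optomechanical device hierarchy
#'
#' A rig is a set of devices (DAQ, amplifier, camera, scanner, laser, stage,
#' microscope) arranged in a forest: each device may name a parent device to
#' which it is physically or optically attached, and carries an affine
#' transform from its own local frame into the parent's frame. Chaining the
#' transforms up to the root expresses any device coordinate (e.g. a camera
#' pixel) in the global coordinate system of the sample. Stages contribute
#' their current position as a translation; microscopes contribute the scale
#' and offset of the active objective, so stage motion and objective changes
#' propagate automatically to every descendant device.
#'
#' Rigs are mutable objects with reference semantics (environments), like a
#' physical rig: \code{\link{move_stage}} and \code{\link{set_objective}}
#' update state in place and notify registered listeners.
#'
#' @param path path to a YAML (or JSON) rig configuration file with a
#'   top-level \code{devices:} list. Each entry has \code{name}, \code{kind}
#'   (daq | clamp | camera | scanner | laser | stage | microscope |
#'   daqgeneric), optional \code{parent}, \code{transform}
#'   (\code{offset}, \code{scale}, \code{angle_deg}), \code{connections}
#'   (channel -> \code{daq}/\code{port}/\code{type}) and kind-specific
#'   settings (\code{objectives:} for microscopes, \code{cell:} for clamps).
#'   Quantities may carry unit suffixes (\code{"100 um"}), normalized on load.
#' @return An object of class \code{"rig"}.
#' @seealso \code{\link{global_transform}}, \code{\link{map_point}}
#' @export
load_rig_config <- function(path) {
  if (!file.exists(path)) stop("rig config not found: ", path)
  cfg <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop("rig config parse error in '",
                                           path, "': ", conditionMessage(e)))
  rig_from_config(cfg)
}

.rig_kinds <- c("daq", "clamp", "camera", "scanner", "laser", "stage",
                "microscope", "daqgeneric")

#' Build a rig from an already-parsed configuration list
#' @param cfg a list with a \code{devices} element (as from
#'   \code{yaml::read_yaml}).
#' @rdname load_rig_config
#' @export
rig_from_config <- function(cfg) {
  if (is.null(cfg$devices)) stop("rig config has no 'devices' list")
  devs <- list()
  for (d in cfg$devices) {
    if (is.null(d$name)) stop("device entry without a name")
    if (d$name %in% names(devs)) stop("duplicate device name: '", d$name, "'")
    kind <- match.arg(d$kind, .rig_kinds)
    tr <- d$transform
    dev <- list(
      name = d$name,
      kind = kind,
      parent = if (is.null(d$parent)) NA_character_ else d$parent,
      offset = if (is.null(tr$offset)) c(0, 0, 0) else si_value(tr$offset),
      scale = if (is.null(tr$scale)) c(1, 1, 1) else si_value(tr$scale),
      angle_deg = if (is.null(tr$angle_deg)) 0 else as.numeric(tr$angle_deg),
      connections = d$connections,
      params = d[setdiff(names(d), c("name", "kind", "parent", "transform",
                                     "connections", "objectives"))]
    )
    if (kind == "stage") dev$position <- dev$offset
    if (kind == "microscope") {
      dev$objectives <- .parse_objectives(d$objectives, d$name)
      dev$active_slot <- if (is.null(d$active_slot)) {
        dev$objectives[[1]]$slot
      } else as.integer(d$active_slot)
      dev$selected <- vapply(dev$objectives,
                             function(s) s$options[[1]]$name, character(1))
      names(dev$selected) <- vapply(dev$objectives,
                                    function(s) as.character(s$slot),
                                    character(1))
    }
    devs[[d$name]] <- dev
  }
  rig <- new.env(parent = emptyenv())
  rig$devices <- devs
  rig$listeners <- list()
  class(rig) <- "rig"
  .validate_rig(rig)
  rig
}

.parse_objectives <- function(objs, scope) {
  if (is.null(objs) || length(objs) == 0L)
    stop("microscope '", scope, "' defines no objectives")
  lapply(objs, function(slot) {
    if (is.null(slot$slot)) stop("objective slot without an index in '",
                                 scope, "'")
    opts <- lapply(slot$options, function(o) {
      sc <- si_value(o$scale)
      if (length(sc) == 1L) sc <- rep(sc, 2L)
      if (any(sc <= 0)) stop("objective '", o$name, "' has non-positive scale")
      list(name = o$name, scale = sc,
           offset = if (is.null(o$offset)) c(0, 0, 0) else si_value(o$offset))
    })
    list(slot = as.integer(slot$slot), options = opts)
  })
}

.validate_rig <- function(rig) {
  devs <- rig$devices
  for (d in devs) {
    if (!is.na(d$parent)) {
      if (identical(d$parent, d$name))
        stop("device '", d$name, "' is its own parent (cycle)")
      if (is.null(devs[[d$parent]]))
        stop("device '", d$name, "' has unknown parent '", d$parent, "'")
    }
    for (ch in names(d$connections)) {
      con <- d$connections[[ch]]
      if (is.null(con$daq) || is.null(devs[[con$daq]]))
        stop("device '", d$name, "' channel '", ch,
             "' references unknown DAQ '", con$daq %||% "<missing>", "'")
      if (devs[[con$daq]]$kind != "daq")
        stop("device '", d$name, "' channel '", ch, "' references '",
             con$daq, "', which is not a DAQ")
    }
  }
  # cycle check: walk each chain with a visited set
  for (nm in names(devs)) {
    seen <- character()
    cur <- nm
    while (!is.na(devs[[cur]]$parent)) {
      if (cur %in% seen) stop("device hierarchy contains a cycle at '",
                              cur, "'")
      seen <- c(seen, cur)
      cur <- devs[[cur]]$parent
    }
  }
  invisible(rig)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.rig <- function(x, ...) {
  cat("<rig> ", length(x$devices), " devices\n", sep = "")
  for (d in x$devices)
    cat(sprintf("  %-12s %-10s parent=%s\n", d$name, d$kind,
                ifelse(is.na(d$parent), "-", d$parent)))
  invisible(x)
}

#' Get one device record
#' @param rig a rig.
#' @param device device name.
#' @export
rig_device <- function(rig, device) {
  d <- rig$devices[[device]]
  if (is.null(d)) stop("unknown device: '", device, "'")
  d
}

#' Names of all devices in a rig
#' @param rig a rig.
#' @export
rig_device_names <- function(rig) names(rig$devices)

#' Chain of ancestors from a device up to its root
#' @inheritParams rig_device
#' @return character vector of parent names, nearest first.
#' @export
parent_chain <- function(rig, device) {
  d <- rig_device(rig, device)
  out <- character()
  while (!is.na(d$parent)) {
    out <- c(out, d$parent)
    d <- rig$devices[[d$parent]]
  }
  out
}

#' Local transform of a device into its parent's frame
#' @inheritParams rig_device
#' @export
local_transform <- function(rig, device) {
  d <- rig_device(rig, device)
  if (d$kind == "microscope") {
    obj <- active_objective(rig, device)
    return(tf_from_parts(obj$offset, c(obj$scale, 1)))
  }
  if (d$kind == "stage") return(tf_translate(d$position))
  tf_from_parts(d$offset, d$scale, d$angle_deg)
}

#' Transform from a device's local frame to the global sample frame
#'
#' The product of local transforms along the parent chain, reflecting the
#' current stage position and active objective. Maps e.g. camera pixel
#' coordinates to physical sample coordinates.
#' @inheritParams rig_device
#' @export
global_transform <- function(rig, device) {
  tf <- local_transform(rig, device)
  for (anc in parent_chain(rig, device))
    tf <- tf_compose(local_transform(rig, anc), tf)
  tf
}

#' Map a point between a device's local frame and the global frame
#' @inheritParams rig_device
#' @param point length-3 numeric (or n x 3 matrix).
#' @param direction \code{"to_global"} or \code{"to_local"}.
#' @export
map_point <- function(rig, device, point,
                      direction = c("to_global", "to_local")) {
  direction <- match.arg(direction)
  tf <- global_transform(rig, device)
  if (direction == "to_local") tf <- tf_invert(tf)
  tf_apply(tf, point)
}

#' Active objective of a microscope
#' @inheritParams rig_device
#' @export
active_objective <- function(rig, device) {
  d <- rig_device(rig, device)
  if (d$kind != "microscope") stop("'", device, "' is not a microscope")
  slot <- Filter(function(s) s$slot == d$active_slot, d$objectives)[[1]]
  sel <- d$selected[[as.character(d$active_slot)]]
  for (o in slot$options) if (o$name == sel) return(c(o, slot = d$active_slot))
  stop("no objective selected in slot ", d$active_slot)
}

.emit <- function(rig, event) {
  for (fn in rig$listeners) fn(event)
  invisible(NULL)
}

#' Register a listener for rig state-change events
#'
#' Listeners are called with a list carrying at least \code{type}
#' (\code{"objective_changed"} or \code{"stage_moved"}) and \code{device}.
#' Calibration consumers use this to switch stored calibrations when the
#' objective changes.
#' @param rig a rig.
#' @param fn function of one argument (the event list).
#' @export
rig_on_event <- function(rig, fn) {
  rig$listeners <- c(rig$listeners, fn)
  invisible(rig)
}

#' Switch the active objective of a microscope
#'
#' Updates the microscope's local transform to the objective's scale and
#' offset; the global mapping of every descendant device (camera, scanner)
#' changes accordingly, and an \code{objective_changed} event is emitted.
#' @inheritParams rig_device
#' @param slot slot index.
#' @param objective objective name registered for that slot.
#' @export
set_objective <- function(rig, device, slot, objective) {
  d <- rig_device(rig, device)
  if (d$kind != "microscope") stop("'", device, "' is not a microscope")
  slots <- vapply(d$objectives, function(s) s$slot, integer(1))
  if (!slot %in% slots) stop("unknown objective slot ", slot, " on '",
                             device, "'")
  opts <- d$objectives[[which(slots == slot)]]$options
  if (!objective %in% vapply(opts, `[[`, character(1), "name"))
    stop("unknown objective '", objective, "' in slot ", slot, " of '",
         device, "'")
  d$active_slot <- as.integer(slot)
  d$selected[[as.character(slot)]] <- objective
  rig$devices[[device]] <- d
  .emit(rig, list(type = "objective_changed", device = device,
                  slot = slot, objective = objective))
  invisible(rig)
}

#' Move a stage to an absolute position
#'
#' Sets the stage's local translation; every descendant's global mapping
#' shifts by the same delta. Emits a \code{stage_moved} event.
#' @inheritParams rig_device
#' @param position length-3 numeric position (m).
#' @export
move_stage <- function(rig, device, position) {
  d <- rig_device(rig, device)
  if (d$kind != "stage") stop("'", device, "' is not a stage")
  position <- rep_len(si_value(position), 3L)
  d$position <- position
  rig$devices[[device]] <- d
  .emit(rig, list(type = "stage_moved", device = device, position = position))
  invisible(rig)
}
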