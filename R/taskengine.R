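#' Validate and normalize a task specification
#'
#' A task describes one synchronized episodic acquisition as a list with a
#' \code{protocol} block (\code{duration} in seconds, \code{storeData},
#' \code{continuous}) plus one block per participating device, holding
#' device-specific commands: DAQ \code{rate}/\code{numPts}, clamp
#' \code{mode}/\code{command}/record flags, camera
#' \code{triggerMode}/\code{frames}/\code{channels}. Any device block may
#' name a \code{triggerDevice}: the device then arms and waits for a
#' hardware edge from that source. Only the protocol block is interpreted by
#' the engine itself; device blocks are interpreted by the devices.
#'
#' Validation resolves device names against the rig, reconciles waveform
#' lengths with \code{rate * duration}, checks the trigger graph is acyclic,
#' rejects continuous acquisition (only episodic tasks are supported), and
#' fills defaults.
#'
#' @param rig a rig.
#' @param spec task specification list (e.g. from \code{yaml::read_yaml}).
#' @return normalized spec with attribute \code{"participants"}.
#' @export
validate_task <- function(rig, spec) {
  if (is.null(spec$protocol)) stop("task has no 'protocol' block")
  p <- spec$protocol
  p$duration <- si_value(p$duration %||% stop("protocol has no duration"))
  if (p$duration <= 0) stop("protocol duration must be > 0")
  if (isTRUE(p$continuous))
    stop("continuous acquisition is not supported (episodic tasks only)")
  p$continuous <- FALSE
  p$storeData <- isTRUE(p$storeData)
  spec$protocol <- p

  participants <- setdiff(names(spec), "protocol")
  for (dv in participants) {
    if (!dv %in% rig_device_names(rig))
      stop("task references unknown device: '", dv, "'")
  }
  # trigger graph: edge triggered -> source; must be acyclic, sources present
  for (dv in participants) {
    trg <- spec[[dv]]$triggerDevice
    if (!is.null(trg) && !trg %in% participants)
      stop("device '", dv, "' is triggered by '", trg,
           "', which is not in the task")
  }
  .check_trigger_acyclic(spec, participants)

  for (dv in participants) {
    blk <- spec[[dv]]
    kind <- rig_device(rig, dv)$kind
    if (kind == "daq") {
      blk$rate <- si_value(blk$rate %||% 40e3)
      want <- round(blk$rate * p$duration)
      if (is.null(blk$numPts)) blk$numPts <- want
      blk$numPts <- as.integer(si_value(blk$numPts))
      if (abs(blk$numPts - want) > 0.5)
        stop("DAQ '", dv, "': numPts (", blk$numPts,
             ") does not match rate * duration (", want, ")")
    }
    if (kind == "clamp") {
      blk$mode <- .norm_clamp_mode(blk$mode %||% "i0")
      if (!is.null(blk$command) && !is.null(blk$command$samples)) {
        # explicit arrays must already match the DAQ timebase
        daq <- .host_daq(rig, dv)
        if (!is.null(daq) && !is.null(spec[[daq]]$rate)) {
          want <- round(si_value(spec[[daq]]$rate) * p$duration)
          if (length(blk$command$samples) != want)
            stop("clamp '", dv, "' command array length ",
                 length(blk$command$samples), " != ", want)
        }
      }
    }
    if (kind == "camera") {
      blk$triggerMode <- tolower(blk$triggerMode %||% "normal")
      if (!blk$triggerMode %in% c("normal", "triggered"))
        stop("camera '", dv, "': unknown triggerMode '", blk$triggerMode, "'")
      blk$frames <- as.integer(blk$frames %||% 5L)
      blk$interval <- si_value(blk$interval %||% (p$duration / blk$frames))
      blk$exposure <- si_value(blk$exposure %||% (0.5 * blk$interval))
    }
    spec[[dv]] <- blk
  }
  structure(spec, participants = participants)
}

.norm_clamp_mode <- function(mode) {
  m <- tolower(gsub("[ =]", "", mode))
  switch(m, "i0" = "i0", "ic" = "ic", "vc" = "vc",
         stop("unknown clamp mode: '", mode, "'"))
}

.check_trigger_acyclic <- function(spec, participants) {
  for (start in participants) {
    seen <- character()
    cur <- start
    repeat {
      trg <- spec[[cur]]$triggerDevice
      if (is.null(trg)) break
      if (trg %in% c(seen, cur))
        stop("trigger cycle involving '", trg, "'")
      seen <- c(seen, cur)
      cur <- trg
    }
  }
}

# DAQ hosting a device's channels, per the rig connection table
.host_daq <- function(rig, device) {
  con <- rig_device(rig, device)$connections
  if (length(con)) con[[1]]$daq else NULL
}

.arming_latency <- function(rig, dv, blk) {
  if (!is.null(blk$arming_latency)) return(si_value(blk$arming_latency))
  switch(rig_device(rig, dv)$kind,
         camera = 0.05, daq = 0.01, clamp = 0.005, scanner = 0.002, 0.001)
}

# Kahn topological sort. edges: list of c(before, after). prefer_late:
# nodes to schedule as late as constraints allow (tie-break).
.toposort <- function(nodes, edges, weight = NULL, prefer_late = character()) {
  indeg <- stats::setNames(rep(0L, length(nodes)), nodes)
  succ <- stats::setNames(vector("list", length(nodes)), nodes)
  for (e in edges) {
    succ[[e[1]]] <- c(succ[[e[1]]], e[2])
    indeg[[e[2]]] <- indeg[[e[2]]] + 1L
  }
  out <- character()
  while (length(out) < length(nodes)) {
    avail <- names(indeg)[indeg == 0L & !names(indeg) %in% out]
    if (length(avail) == 0L) stop("ordering constraints contain a cycle")
    cand <- setdiff(avail, prefer_late)
    if (length(cand) == 0L) cand <- avail
    if (!is.null(weight))
      cand <- cand[order(-weight[cand], cand)]
    else cand <- sort(cand)
    pick <- cand[1]
    out <- c(out, pick)
    indeg[pick] <- -1L
    for (s in succ[[pick]]) indeg[[s]] <- indeg[[s]] - 1L
  }
  out
}

#' Plan device configure and start orders for a task
#'
#' Configure order: a topological order of the declared configure-before
#' preferences (devices whose channels are hosted on a DAQ are configured
#' before that DAQ, so their waveforms are in place when the DAQ programs
#' its buffers), breaking ties by descending arming latency so slow-arming
#' devices (cameras) are configured as early as possible.
#'
#' Start order: every triggered device is started (armed) before its
#' trigger source; DAQ-hosted passive devices arm before their host DAQ;
#' free-running master devices start last.
#'
#' @param rig a rig.
#' @param spec a validated task spec (see \code{\link{validate_task}}).
#' @return list with \code{configure} and \code{start} character vectors.
#' @export
plan_orders <- function(rig, spec) {
  parts <- attr(spec, "participants") %||% setdiff(names(spec), "protocol")
  lat <- vapply(parts, function(dv) .arming_latency(rig, dv, spec[[dv]]),
                numeric(1))
  names(lat) <- parts
  cfg_edges <- list()
  start_edges <- list()
  sources <- character()
  for (dv in parts) {
    blk <- spec[[dv]]
    kind <- rig_device(rig, dv)$kind
    daq <- .host_daq(rig, dv)
    if (!is.null(daq) && daq %in% parts && !identical(daq, dv)) {
      cfg_edges <- c(cfg_edges, list(c(dv, daq)))
      # passive channel devices arm with/before their host DAQ
      if (kind %in% c("clamp", "daqgeneric", "scanner", "laser"))
        start_edges <- c(start_edges, list(c(dv, daq)))
    }
    for (b in blk$configure_before)
      cfg_edges <- c(cfg_edges, list(c(dv, b)))
    if (!is.null(blk$triggerDevice)) {
      start_edges <- c(start_edges, list(c(dv, blk$triggerDevice)))
      sources <- c(sources, blk$triggerDevice)
    }
  }
  configure <- .toposort(parts, cfg_edges, weight = lat)
  start <- .toposort(parts, start_edges, prefer_late = unique(sources))
  list(configure = configure, start = start)
}

#' Execute one task on the simulated rig
#'
#' Reserves all participating devices (released on every exit path),
#' configures them in the planned order, starts them in trigger-safe order,
#' collects per-device results keyed by device name, and optionally stores
#' them in the manager's session. Episodic only: every recorded trace spans
#' the protocol duration.
#'
#' @param mgr a \code{\link{rig_manager}}.
#' @param spec task specification (validated internally).
#' @param seed integer seed; per-device seeds are derived from it.
#' @param scenes optional named list of scene functions for cameras.
#' @param abort_at if non-NULL, simulated time (s) at which an abort request
#'   arrives; devices are stopped in reverse start order and the result
#'   status is \code{"aborted"}.
#' @return list of class \code{"task_result"}: \code{status}
#'   (completed | aborted | failed), \code{results} (per device),
#'   \code{timing} (orders, duration, event log), \code{partial} flag.
#' @export
execute_task <- function(mgr, spec, seed = NULL, scenes = NULL,
                         abort_at = NULL) {
  rig <- mgr$rig
  spec <- validate_task(rig, spec)
  parts <- attr(spec, "participants")
  duration <- spec$protocol$duration
  res <- reserve_devices(mgr, parts, owner = "task")
  on.exit(release_reservation(mgr, res), add = TRUE)
  orders <- plan_orders(rig, spec)
  log <- character()
  for (dv in orders$configure) log <- c(log, paste0("configure:", dv))

  # DAQ timebase shared by analog channels
  daqs <- parts[vapply(parts, function(d) rig_device(rig, d)$kind == "daq",
                       logical(1))]
  rate <- if (length(daqs)) spec[[daqs[1]]]$rate else 20e3
  npts <- round(rate * duration)

  results <- list()
  status <- "completed"
  partial <- FALSE
  for (i in seq_along(orders$start)) {
    dv <- orders$start[i]
    if (isTRUE(rig_device(rig, dv)$params$fail_at_start)) {
      log <- c(log, paste0("fail:", dv))
      status <- "failed"
      partial <- TRUE
      break
    }
    log <- c(log, paste0("start:", dv))
  }

  if (status == "completed" && !is.null(abort_at) && abort_at < duration) {
    status <- "aborted"
    for (dv in rev(orders$start)) log <- c(log, paste0("stop:", dv))
  }

  if (status == "completed") {
    dev_seed <- function(k) if (is.null(seed)) NULL else seed + k
    for (k in seq_along(parts)) {
      dv <- parts[k]
      blk <- spec[[dv]]
      kind <- rig_device(rig, dv)$kind
      if (kind == "clamp") {
        cellp <- rig_device(rig, dv)$params$cell
        cell <- if (is.null(cellp)) cell_model() else
          do.call(cell_model, lapply(cellp, si_value))
        units <- if (blk$mode == "vc") "V" else "A"
        cmd <- build_waveform(blk$command, rate, npts,
                              holding = blk$holding %||% 0)
        cmd_tr <- new_trace(cmd, rate, 0, units, "command")
        out <- sim_clamp_response(cell, cmd_tr, blk$mode, dev_seed(k))
        entry <- list(command = cmd_tr)
        if (isTRUE(blk$primary$record) || is.null(blk$primary))
          entry$primary <- out
        results[[dv]] <- entry
      } else if (kind == "camera") {
        fs <- sim_camera_acquire(
          rig, dv, n_frames = blk$frames, exposure = blk$exposure,
          interval = blk$interval, trigger_mode = blk$triggerMode,
          scene = scenes[[dv]] %||% function(x, y) 0 * x,
          ttl_rate = rate, seed = dev_seed(k))
        entry <- list(frames = fs)
        if (isTRUE(blk$channels$exposure$record)) {
          ttl <- fs$ttl$samples
          ttl <- if (length(ttl) >= npts) ttl[seq_len(npts)] else
            c(ttl, numeric(npts - length(ttl)))
          entry$exposure <- new_trace(ttl, rate, 0, "TTL", "exposure")
        }
        results[[dv]] <- entry
      } else if (kind == "daq") {
        hosted <- parts[vapply(parts, function(d)
          identical(.host_daq(rig, d), dv), logical(1))]
        results[[dv]] <- list(rate = rate, numPts = npts,
                              channels = hosted)
      } else if (kind == "scanner") {
        results[[dv]] <- list(position = si_value(blk$position %||% c(0, 0)))
      } else {
        results[[dv]] <- list(configured = TRUE)
      }
    }
    for (dv in rev(orders$start)) log <- c(log, paste0("stop:", dv))
  }

  out <- structure(list(status = status, results = results,
                        timing = list(duration = duration, rate = rate,
                                      configure_order = orders$configure,
                                      start_order = orders$start,
                                      log = log),
                        partial = partial),
                   class = "task_result")
  if (status == "completed" && spec$protocol$storeData &&
      !is.null(mgr$session)) {
    run_dir <- create_child_dir(mgr$session, "protocol_run",
                                metadata = list(duration = duration,
                                                rate = rate))
    store_task_result(run_dir, out)
    out$stored_in <- run_dir$path
  }
  out
}

#' @export
print.task_result <- function(x, ...) {
  cat("<task_result>", x$status, "-", length(x$results), "device entries\n")
  invisible(x)
}

#' Execute a multi-dimensional parameter sequence of tasks
#'
#' Runs the base task once per point of the Cartesian grid defined by the
#' axes, first axis outermost. All tasks share the base protocol duration.
#'
#' @param mgr a \code{\link{rig_manager}}.
#' @param base base task spec.
#' @param axes list of axes, each \code{list(device =, path =, values =)}
#'   where \code{path} is a character vector into the device block.
#' @param seed base seed; point \code{k} uses \code{seed + k}.
#' @param halt_on_error stop at the first failed point (default: record the
#'   error and continue).
#' @param ... passed on to \code{\link{execute_task}}.
#' @return list of class \code{"sequence_result"}: \code{results} (a list
#'   with \code{dim} = axis lengths), \code{params} (per-point values),
#'   \code{dims}.
#' @export
run_sequence <- function(mgr, base, axes, seed = NULL,
                         halt_on_error = FALSE, ...) {
  if (length(axes) == 0L) stop("sequence needs at least one axis")
  dims <- vapply(axes, function(a) length(a$values), integer(1))
  npts <- prod(dims)
  results <- vector("list", npts)
  params <- vector("list", npts)
  stride <- cumprod(c(1L, dims[-length(dims)]))
  for (k in seq_len(npts)) {
    # mixed radix, last axis fastest => first axis outermost
    rem <- k - 1L
    idx <- integer(length(dims))
    for (a in rev(seq_along(dims))) {
      idx[a] <- rem %% dims[a] + 1L
      rem <- rem %/% dims[a]
    }
    lin <- sum((idx - 1L) * stride) + 1L  # column-major slot for [idx]
    spec <- base
    pv <- list()
    for (a in seq_along(axes)) {
      ax <- axes[[a]]
      val <- ax$values[[idx[a]]]
      spec[[ax$device]] <- .assign_path(spec[[ax$device]], ax$path, val)
      pv[[paste(c(ax$device, ax$path), collapse = ".")]] <- val
    }
    params[[lin]] <- pv
    r <- tryCatch(
      execute_task(mgr, spec, seed = if (is.null(seed)) NULL else seed + k,
                   ...),
      error = function(e) {
        if (halt_on_error) stop(e)
        structure(list(status = "failed", error = conditionMessage(e),
                       results = list(), partial = TRUE),
                  class = "task_result")
      })
    results[[lin]] <- r
  }
  dim(results) <- dims
  dim(params) <- dims
  structure(list(results = results, params = params, dims = dims),
            class = "sequence_result")
}

.assign_path <- function(lst, path, value) {
  if (length(path) == 0L) stop("empty substitution path")
  if (length(path) == 1L) {
    lst[[path]] <- value
    return(lst)
  }
  if (is.null(lst[[path[1]]])) lst[[path[1]]] <- list()
  lst[[path[1]]] <- .assign_path(lst[[path[1]]], path[-1], value)
  lst
}
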