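#' Acquisition manager: device registry and reservations
#'
#' The manager owns a rig and arbitrates access to its devices so that
#' concurrently submitted tasks never touch the same hardware at once.
#' Reservations are granted atomically: either every requested device is
#' claimed under one registry update, or the request joins a first-come,
#' first-served queue. Because all devices are claimed in one step there is
#' no hold-and-wait, so deadlock is impossible by construction.
#'
#' A claim/release ledger (\code{manager$ledger}) records every transition
#' for auditing reservation safety.
#'
#' @param rig a \code{\link{load_rig_config}} rig.
#' @param session optional \code{\link{init_session}} directory handle used
#'   by tasks with \code{storeData}.
#' @return an environment of class \code{"rig_manager"}.
#' @export
rig_manager <- function(rig, session = NULL) {
  mgr <- new.env(parent = emptyenv())
  mgr$rig <- rig
  mgr$claims <- character()     # device name -> owner id
  mgr$queue <- list()           # FIFO of pending reservation envs
  mgr$ledger <- data.frame(event = character(), owner = character(),
                           devices = character(), stringsAsFactors = FALSE)
  mgr$next_id <- 1L
  mgr$session <- session
  class(mgr) <- "rig_manager"
  mgr
}

.log_ledger <- function(mgr, event, owner, devices) {
  mgr$ledger <- rbind(mgr$ledger, data.frame(
    event = event, owner = owner,
    devices = paste(sort(devices), collapse = ","),
    stringsAsFactors = FALSE))
}

#' Reserve a set of devices
#'
#' If every requested device is free the reservation is granted immediately
#' and atomically. Otherwise the request is queued (FIFO); it is granted by
#' a later \code{\link{release_reservation}} once all its devices are free
#' and no earlier queued request is waiting for any of them. In a
#' single-threaded session \code{wait = TRUE} with devices held by another
#' live reservation raises a starvation timeout error, since nothing can
#' release them meanwhile.
#'
#' @param mgr a \code{\link{rig_manager}}.
#' @param devices character vector of device names (duplicates collapsed).
#' @param owner label of the requesting task.
#' @param wait if FALSE, return a pending handle instead of erroring when
#'   the devices are busy.
#' @return a reservation (list with \code{id}, \code{devices},
#'   \code{granted}); pending handles have \code{granted = FALSE} and are
#'   promoted in place (environment semantics) when granted.
#' @export
reserve_devices <- function(mgr, devices, owner = "task", wait = TRUE) {
  devices <- unique(as.character(devices))
  unknown <- setdiff(devices, rig_device_names(mgr$rig))
  if (length(unknown))
    stop("cannot reserve unknown device(s): ", paste(unknown, collapse = ", "))
  res <- new.env(parent = emptyenv())
  res$id <- sprintf("%s#%d", owner, mgr$next_id)
  mgr$next_id <- mgr$next_id + 1L
  res$devices <- devices
  res$granted <- FALSE
  class(res) <- "reservation"
  # a request must also queue behind earlier waiters that overlap it (FIFO)
  queued_devs <- unlist(lapply(mgr$queue, function(q) q$devices))
  busy <- intersect(devices, c(names(mgr$claims), queued_devs))
  if (length(busy) == 0L) {
    mgr$claims[devices] <- res$id
    res$granted <- TRUE
    .log_ledger(mgr, "claim", res$id, devices)
  } else if (wait) {
    # single-threaded session: nothing can release these devices while we
    # block, so waiting is certain starvation -- fail immediately
    stop("reservation timeout: device(s) busy: ",
         paste(busy, collapse = ", "))
  } else {
    mgr$queue <- c(mgr$queue, list(res))
    .log_ledger(mgr, "queue", res$id, devices)
  }
  res
}

#' Release a reservation and grant queued requests in order
#' @param mgr a \code{\link{rig_manager}}.
#' @param res a granted reservation.
#' @export
release_reservation <- function(mgr, res) {
  if (!isTRUE(res$granted)) {
    # cancel a pending request
    mgr$queue <- Filter(function(q) !identical(q$id, res$id), mgr$queue)
    return(invisible(NULL))
  }
  mgr$claims <- mgr$claims[!names(mgr$claims) %in% res$devices]
  res$granted <- FALSE
  .log_ledger(mgr, "release", res$id, res$devices)
  # serve the queue first-come-first-served; a blocked head does not let
  # later arrivals overtake it on the devices it is waiting for
  blocked <- character()
  remaining <- list()
  for (q in mgr$queue) {
    if (length(intersect(q$devices, c(names(mgr$claims), blocked))) == 0L) {
      mgr$claims[q$devices] <- q$id
      q$granted <- TRUE
      .log_ledger(mgr, "claim", q$id, q$devices)
    } else {
      blocked <- union(blocked, q$devices)
      remaining <- c(remaining, list(q))
    }
  }
  mgr$queue <- remaining
  invisible(NULL)
}

#' @export
print.rig_manager <- function(x, ...) {
  cat("<rig_manager> claims:", length(x$claims),
      "queued:", length(x$queue), "\n")
  invisible(x)
}
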