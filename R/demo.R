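#' Build the demonstration rig and example task files
#'
#' Writes a complete simulated-rig configuration (stage -> microscope ->
#' {camera, scanner} plus a DAQ, a patch-clamp channel with a model cell,
#' and a laser) and the canonical example task: record 100 ms at 40 kHz
#' from the clamp's primary channel while the camera free-runs and triggers
#' the DAQ, with the exposure TTL recorded. Fully reproducible: the files
#' depend only on the seed.
#'
#' @param out_dir directory to write \code{rig.yaml} and
#'   \code{example_task.yaml} into (created if missing).
#' @param seed integer seed recorded in the rig for simulation noise.
#' @return list with \code{rig} (loaded rig), \code{rig_path},
#'   \code{task_path}, \code{task} (parsed spec).
#' @export
build_demo_rig <- function(out_dir, seed = 0L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rig_cfg <- list(devices = list(
    list(name = "DAQ", kind = "daq"),
    list(name = "Stage", kind = "stage",
         transform = list(offset = c(0, 0, 0))),
    list(name = "Microscope", kind = "microscope", parent = "Stage",
         objectives = list(
           list(slot = 0L, options = list(
             list(name = "5x", scale = c(2e-6, 2e-6),
                  offset = c(0, 0, 0)))),
           list(slot = 1L, options = list(
             list(name = "63x", scale = c(1.59e-7, 1.59e-7),
                  offset = c(7e-5, 6.5e-5, 0))))),
         active_slot = 0L),
    list(name = "Camera", kind = "camera", parent = "Microscope",
         connections = list(
           exposure = list(daq = "DAQ", port = "di0", type = "di"),
           trigger = list(daq = "DAQ", port = "pfi0", type = "do"))),
    list(name = "Scanner", kind = "scanner", parent = "Microscope",
         connections = list(
           vx = list(daq = "DAQ", port = "ao2", type = "ao"),
           vy = list(daq = "DAQ", port = "ao3", type = "ao"))),
    list(name = "Laser", kind = "laser",
         connections = list(
           shutter = list(daq = "DAQ", port = "do1", type = "do")),
         power = 0.02, attenuation = list("5x" = 0.5, "63x" = 0.12)),
    list(name = "Clamp1", kind = "clamp",
         connections = list(
           command = list(daq = "DAQ", port = "ao0", type = "ao"),
           primary = list(daq = "DAQ", port = "ai0", type = "ai")),
         cell = list(Ra = 10e6, Rm = 100e6, Cm = 30e-12,
                     Vrest = -65e-3, noise_sd = 0),
         seed = seed)))
  task <- list(
    protocol = list(storeData = FALSE, continuous = FALSE, duration = 0.1),
    DAQ = list(rate = 40e3, numPts = 4e3, triggerDevice = "Camera"),
    Clamp1 = list(mode = "I=0",
                  primary = list(mode = "MembranePotential", record = TRUE)),
    Camera = list(record = TRUE, triggerMode = "Normal",
                  channels = list(exposure = list(record = TRUE))))
  rig_path <- file.path(out_dir, "rig.yaml")
  task_path <- file.path(out_dir, "example_task.yaml")
  yaml::write_yaml(rig_cfg, rig_path)
  yaml::write_yaml(task, task_path)
  list(rig = rig_from_config(rig_cfg), rig_path = rig_path,
       task_path = task_path, task = task)
}
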