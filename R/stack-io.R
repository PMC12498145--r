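#' Time-gated image stack
#'
#' The central data container: a `n_gates x H x W` array of non-negative camera
#' counts (stored as doubles, since demodulated components and Monte Carlo
#' outputs are real-valued) together with the acquisition configuration, the
#' detector pixel pitch, and a free-form provenance record (pattern frequency,
#' phase index, RNG seed, phantom id, ...).
#'
#' @param data numeric array, `dim = c(n_gates, H, W)`, finite and `>= 0`.
#' @param config an [acq_config()]; `config$n_gates` must match `dim(data)[1]`.
#' @param pixel_pitch_mm detector pixel pitch (mm / pixel).
#' @param provenance named list of free metadata.
#' @return An object of class `gated_stack`.
#' @export
gated_stack <- function(data, config, pixel_pitch_mm, provenance = list()) {
  stopifnot(inherits(config, "acq_config"))
  data <- as.array(data)
  if (length(dim(data)) == 2) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 3)
    stop("gated_stack data must be a T x H x W array", call. = FALSE)
  if (dim(data)[1] != config$n_gates)
    stop("gated_stack data has ", dim(data)[1], " gates but config declares ",
         config$n_gates, call. = FALSE)
  if (anyNA(data) || any(!is.finite(data)))
    stop("gated_stack data must be finite", call. = FALSE)
  if (any(data < 0))
    stop("gated_stack data must be non-negative", call. = FALSE)
  if (!is.finite(pixel_pitch_mm) || pixel_pitch_mm <= 0)
    stop("pixel_pitch_mm must be > 0", call. = FALSE)
  structure(list(data = data, config = config,
                 pixel_pitch_mm = pixel_pitch_mm, provenance = provenance),
            class = "gated_stack")
}

#' @export
print.gated_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<gated_stack> %d gates x %d x %d px, pitch %g mm, peak %g counts\n",
              d[1], d[2], d[3], x$pixel_pitch_mm, max(x$data)))
  invisible(x)
}

# required header attributes of the native container
.stack_attrs <- c("n_gates", "gate_width_ps", "gate_step_ps", "t0_ps",
                  "laser_period_ns", "pixel_pitch_mm")

#' Write / read a gated stack (native container)
#'
#' The native on-disk format is a single self-describing binary file: a magic
#' string, a length-prefixed JSON header holding the acquisition attributes
#' (`gate_width_ps`, `gate_step_ps`, `t0_ps`, `laser_period_ns`,
#' `pixel_pitch_mm`, array dimensions, provenance), then the image data as
#' little-endian float64 in gate-major order. Round-tripping is bit-exact for
#' both counts and metadata. For plain-text interchange see
#' [write_stack_csv()].
#'
#' @param stack a [gated_stack()].
#' @param path file path to write / read.
#' @return `read_stack()` returns a [gated_stack()]; `write_stack()` returns
#'   `path` invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "gated_stack"))
  cfg <- stack$config
  header <- list(n_gates = cfg$n_gates, gate_width_ps = cfg$gate_width_ps,
                 gate_step_ps = cfg$gate_step_ps, t0_ps = cfg$t0_ps,
                 laser_period_ns = cfg$laser_period_ns,
                 mcp_voltage = cfg$mcp_voltage, binning = cfg$binning,
                 pixel_pitch_mm = stack$pixel_pitch_mm,
                 dim = dim(stack$data), provenance = stack$provenance)
  hjson <- charToRaw(as.character(
    jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA, null = "null")))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("HSFLIMGS"), con)
  writeBin(as.integer(length(hjson)), con, size = 4L, endian = "little")
  writeBin(hjson, con)
  writeBin(as.vector(stack$data), con, size = 8L, endian = "little")
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 8L))
  if (!identical(magic, "HSFLIMGS"))
    stop("format error: '", path, "' is not a gated-stack container", call. = FALSE)
  hlen <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  header <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", hlen)),
                               simplifyVector = TRUE)
  missing <- setdiff(.stack_attrs, names(header))
  if (length(missing))
    stop("format error: missing required attribute(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  d <- as.integer(header$dim)
  data <- readBin(con, "double", prod(d), size = 8L, endian = "little")
  dim(data) <- d
  cfg <- acq_config(n_gates = as.integer(header$n_gates),
                    gate_width_ps = as.numeric(header$gate_width_ps),
                    gate_step_ps = as.numeric(header$gate_step_ps),
                    t0_ps = as.numeric(header$t0_ps),
                    laser_period_ns = as.numeric(header$laser_period_ns),
                    mcp_voltage = if (is.null(header$mcp_voltage)) NA else header$mcp_voltage,
                    binning = if (is.null(header$binning)) 1L else header$binning)
  prov <- header$provenance
  if (is.null(prov) || length(prov) == 0) prov <- list()
  gated_stack(data, cfg, header$pixel_pitch_mm, provenance = as.list(prov))
}

#' Plain-text (CSV) interchange for gated stacks
#'
#' Long-format CSV with columns `gate,row,col,value` and the required header
#' attributes as `#`-prefixed comment lines. Values are written in full
#' precision (`%.17g`), so the array round-trips exactly; intended for
#' interchange with other tools, not as the native container.
#'
#' @inheritParams write_stack
#' @export
write_stack_csv <- function(stack, path) {
  stopifnot(inherits(stack, "gated_stack"))
  cfg <- stack$config
  d <- dim(stack$data)
  hdr <- c(sprintf("# n_gates=%d", cfg$n_gates),
           sprintf("# gate_width_ps=%.17g", cfg$gate_width_ps),
           sprintf("# gate_step_ps=%.17g", cfg$gate_step_ps),
           sprintf("# t0_ps=%.17g", cfg$t0_ps),
           sprintf("# laser_period_ns=%.17g", cfg$laser_period_ns),
           sprintf("# pixel_pitch_mm=%.17g", stack$pixel_pitch_mm),
           sprintf("# dim=%d,%d,%d", d[1], d[2], d[3]))
  idx <- arrayInd(seq_along(stack$data), d)
  body <- sprintf("%d,%d,%d,%.17g", idx[, 1], idx[, 2], idx[, 3],
                  as.vector(stack$data))
  writeLines(c(hdr, "gate,row,col,value", body), path)
  invisible(path)
}

#' @rdname write_stack_csv
#' @export
read_stack_csv <- function(path) {
  lines <- readLines(path)
  hmask <- startsWith(lines, "#")
  kv <- sub("^# *", "", lines[hmask])
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  names(vals) <- keys
  missing <- setdiff(.stack_attrs, keys)
  if (length(missing))
    stop("format error: missing required attribute(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  d <- as.integer(strsplit(vals[["dim"]], ",")[[1]])
  tab <- read.csv(text = lines[!hmask])
  data <- array(0, d)
  data[cbind(tab$gate, tab$row, tab$col)] <- tab$value
  cfg <- acq_config(n_gates = as.integer(vals[["n_gates"]]),
                    gate_width_ps = as.numeric(vals[["gate_width_ps"]]),
                    gate_step_ps = as.numeric(vals[["gate_step_ps"]]),
                    t0_ps = as.numeric(vals[["t0_ps"]]),
                    laser_period_ns = as.numeric(vals[["laser_period_ns"]]))
  gated_stack(data, cfg, as.numeric(vals[["pixel_pitch_mm"]]))
}

# md5 of a serialized object via a scratch file; used for reproducibility
# contracts (same config + seed => same hash)
object_hash <- function(x) {
  f <- tempfile(fileext = ".rds")
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}
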