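# Frame and sequence I/O. Frames travel as plain-text PGM (P2) so fixtures
# stay text-only; intensities are scaled to 8-bit on write and back to [0, 1]
# on read.

#' Read / write plain-text PGM (P2) grayscale images
#'
#' @param frame numeric matrix; values are clipped to [lo, hi] then scaled to
#'   0..255.
#' @param path file path.
#' @param lo,hi intensity range mapped onto 0..255.
#' @return `read_pgm` returns a matrix in [0, 1]; `write_pgm` returns `path`
#'   invisibly.
#' @export
write_pgm <- function(frame, path, lo = 0, hi = 1) {
  stopifnot(is.matrix(frame), hi > lo)
  px <- round(clamp((frame - lo) / (hi - lo), 0, 1) * 255)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(frame), nrow(frame)), "255"), con)
  writeLines(apply(px, 1L, paste, collapse = " "), con)
  invisible(path)
}

#' @rdname write_pgm
#' @export
read_pgm <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (toks[1] != "P2") stop("only plain-text PGM (P2) supported", call. = FALSE)
  W <- as.integer(toks[2]); H <- as.integer(toks[3])
  maxval <- as.numeric(toks[4])
  vals <- as.numeric(toks[-(1:4)])
  stopifnot(length(vals) == H * W)
  matrix(vals, H, W, byrow = TRUE) / maxval
}

#' Save / load an image sequence directory
#'
#' Frames are written as numbered PGM files (frame_0001.pgm, ...) with a JSON
#' manifest alongside.
#'
#' @param frames list of matrices.
#' @param dir directory (created if missing).
#' @param manifest list stored as manifest.json.
#' @return `save_sequence_dir` returns `dir` invisibly; `load_sequence_dir`
#'   returns list(frames, manifest).
#' @export
save_sequence_dir <- function(frames, dir, manifest = list()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (i in seq_along(frames))
    write_pgm(frames[[i]], file.path(dir, sprintf("frame_%04d.pgm", i)))
  manifest$n_frames <- length(frames)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname save_sequence_dir
#' @export
load_sequence_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.pgm$", full.names = TRUE))
  if (length(files) == 0L) stop("no .pgm frames in ", dir, call. = FALSE)
  mf <- file.path(dir, "manifest.json")
  manifest <- if (file.exists(mf)) jsonlite::read_json(mf) else list()
  list(frames = lapply(files, read_pgm), manifest = manifest)
}

# --- model container -------------------------------------------------------
# Single-file versioned container: plain-text header lines plus little-endian
# float64 payloads. Writing is fully deterministic, so retraining with the
# same inputs yields byte-identical files.

write_template_block <- function(template, con) {
  dp <- template$dict_params
  hdr <- c(sprintf("frame_shape %d %d", template$frame_shape[1],
                   template$frame_shape[2]),
           sprintf("dict %d %d %d %.17g %.17g %.17g", dp$n_orientations,
                   dp$n_scales, dp$base_size, dp$omega0, dp$scale_step,
                   dp$gamma),
           sprintf("saturation %.17g", template$saturation),
           sprintf("bounds %d %d", template$bounds$location,
                   template$bounds$orientation),
           sprintf("n_elements %d", template$n_elements),
           vapply(template$elements, function(e)
             sprintf("element %d %d %d %d %d", e$row - 1L, e$col - 1L,
                     e$orientation_index, e$scale_index, e$inhibition_radius),
             character(1)),
           sprintf("payload %d", 3L * template$n_elements))
  writeLines(hdr, con)
  writeBin(as.numeric(c(template$weights, template$log_normalizers,
                        template$selection_gains)), con, size = 8L,
           endian = "little")
}

read_text_line <- function(con) {
  chars <- raw(0)
  repeat {
    b <- readBin(con, "raw", 1L)
    if (length(b) == 0L || b == as.raw(10L)) break
    chars <- c(chars, b)
  }
  rawToChar(chars)
}

read_template_block <- function(con) {
  fs <- as.integer(strsplit(read_text_line(con), " ")[[1]][2:3])
  dv <- strsplit(read_text_line(con), " ")[[1]][-1]
  dp <- list(n_orientations = as.integer(dv[1]), n_scales = as.integer(dv[2]),
             base_size = as.integer(dv[3]), omega0 = as.numeric(dv[4]),
             scale_step = as.numeric(dv[5]), gamma = as.numeric(dv[6]))
  sat <- as.numeric(strsplit(read_text_line(con), " ")[[1]][2])
  bv <- as.integer(strsplit(read_text_line(con), " ")[[1]][2:3])
  k <- as.integer(strsplit(read_text_line(con), " ")[[1]][2])
  dict <- do.call(build_gabor_dictionary, dp)
  elements <- vector("list", k)
  for (i in seq_len(k)) {
    ev <- as.integer(strsplit(read_text_line(con), " ")[[1]][-1])
    el <- dict_element(dict, ev[3], ev[4])
    elements[[i]] <- list(row = ev[1] + 1L, col = ev[2] + 1L,
                          orientation_index = ev[3], scale_index = ev[4],
                          orientation = el$orientation,
                          inhibition_radius = ev[5])
  }
  np <- as.integer(strsplit(read_text_line(con), " ")[[1]][2])
  payload <- readBin(con, "numeric", np, size = 8L, endian = "little")
  structure(list(elements = elements, weights = payload[seq_len(k)],
                 log_normalizers = payload[k + seq_len(k)],
                 selection_gains = payload[2L * k + seq_len(k)],
                 n_elements = k, bounds = abm_bounds(bv[1], bv[2]),
                 saturation = sat, frame_shape = fs, dict_params = dp),
            class = "abm_template")
}

#' Serialize / deserialize a trained model
#'
#' One versioned file holding the class list, configuration, one active basis
#' template per class, and the prototype bank (V, adjoint, labels, penalty).
#' Writing is deterministic: identical models give byte-identical files.
#'
#' @param model a `biomotion_model` from [train_model()].
#' @param path file path.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "biomotion_model"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines("BIOMOTION_MODEL v1", con)
  classes <- names(model$class_groups)
  writeLines(sprintf("classes %d", length(classes)), con)
  for (cl in classes)
    writeLines(sprintf("class %s %s", cl, model$class_groups[[cl]]), con)
  cfg_lines <- config_to_lines(model$config)
  writeLines(sprintf("config %d", length(cfg_lines)), con)
  writeLines(cfg_lines, con)
  for (cl in classes) {
    writeLines(sprintf("template %s", cl), con)
    write_template_block(model$templates[[cl]], con)
  }
  b <- model$bank
  writeLines(sprintf("bank %d %d", nrow(b$V), ncol(b$V)), con)
  writeLines(sprintf("labels %s", paste(b$labels, collapse = " ")), con)
  if (is.null(b$penalty)) writeLines("penalty none", con)
  else writeLines(sprintf("penalty %.17g %.17g", b$penalty$P1, b$penalty$P2),
                  con)
  writeLines(sprintf("payload %d",
                     length(b$V) + length(b$V_adj)), con)
  writeBin(as.numeric(c(b$V, b$V_adj)), con, size = 8L, endian = "little")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  stopifnot(read_text_line(con) == "BIOMOTION_MODEL v1")
  ncl <- as.integer(strsplit(read_text_line(con), " ")[[1]][2])
  class_groups <- character(0)
  for (i in seq_len(ncl)) {
    cv <- strsplit(read_text_line(con), " ")[[1]]
    class_groups[cv[2]] <- cv[3]
  }
  ncfg <- as.integer(strsplit(read_text_line(con), " ")[[1]][2])
  config <- config_from_lines(vapply(seq_len(ncfg), function(i)
    read_text_line(con), character(1)))
  templates <- list()
  for (i in seq_len(ncl)) {
    tv <- strsplit(read_text_line(con), " ")[[1]]
    templates[[tv[2]]] <- read_template_block(con)
  }
  bv <- as.integer(strsplit(read_text_line(con), " ")[[1]][2:3])
  labels <- strsplit(read_text_line(con), " ")[[1]][-1]
  ptoks <- strsplit(read_text_line(con), " ")[[1]][-1]
  penalty <- if (identical(ptoks[1], "none")) NULL
  else list(P1 = as.numeric(ptoks[1]), P2 = as.numeric(ptoks[2]))
  np <- as.integer(strsplit(read_text_line(con), " ")[[1]][2])
  payload <- readBin(con, "numeric", np, size = 8L, endian = "little")
  nV <- bv[1] * bv[2]
  V <- matrix(payload[seq_len(nV)], bv[1], bv[2])
  V_adj <- matrix(payload[nV + seq_len(np - nV)], ncol = bv[1])
  bank <- structure(list(V = V, V_adj = V_adj, labels = labels,
                         row_labels = if (is.null(penalty)) labels
                         else unique(labels),
                         penalty = penalty),
                    class = "prototype_bank")
  structure(list(class_groups = class_groups, templates = templates,
                 bank = bank, config = config),
            class = "biomotion_model")
}
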