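#' Active basis model: sparse deformable Gabor templates
#'
#' A template is a small ordered set of Gabor elements, each with a weight
#' delta_i and a log-normalizer log Phi(delta_i), scored as a log-likelihood
#' ratio: M = sum_i delta_i * h_i - sum_i log Phi(delta_i), where h_i is the
#' locally max-pooled saturated response of element i (each element may
#' perturb slightly in location and orientation). Templates are learned by the
#' shared sketch algorithm: greedy matching-pursuit selection of the dictionary
#' placement maximizing the summed pooled response across all training frames,
#' with local inhibition of nearby placements after each pick.
#'
#' @name abm
NULL

#' Saturating transform of a response map
#'
#' Implements the response transform chain: whitening (division of the squared
#' response by its frame mean square), then a sigmoid saturation bounded by
#' `saturation`, fixing 0 at 0 and monotone increasing.
#'
#' @param response non-negative magnitude response map.
#' @param saturation upper bound zeta (> 0), default 6.
#' @param whiten_margin border width excluded from the whitening statistic.
#'   Zero-padded correlation makes border responses depend on the frame's DC
#'   level; whitening over the interior keeps template scores invariant to
#'   additive intensity shifts.
#' @return transformed map, elementwise in [0, saturation).
#' @export
saturate_response <- function(response, saturation = 6, whiten_margin = 0L,
                              mean_square = NULL) {
  stopifnot(saturation > 0)
  ms <- if (!is.null(mean_square)) mean_square else {
    H <- nrow(response); W <- ncol(response)
    g <- whiten_margin
    core <- if (g > 0L && 2L * g < min(H, W))
      response[(g + 1L):(H - g), (g + 1L):(W - g)] else response
    mean(core^2)
  }
  if (ms <= 0) return(response * 0)
  w <- response^2 / ms
  saturation * (2 / (1 + exp(-2 * w / saturation)) - 1)
}

# Saturated response maps of every dictionary element on one frame.
# Whitening uses ONE frame-level mean-square statistic shared by all element
# maps (interior margin only): per-map whitening would normalize away the
# orientation selectivity that the selection step depends on.
abm_response_stack <- function(frame, dictionary, saturation = 6) {
  margin <- (max(dictionary$kernel_sizes) - 1L) %/% 2L
  raw <- gabor_respond_all(frame, dictionary)
  H <- nrow(frame); W <- ncol(frame)
  g <- if (2L * margin < min(H, W)) margin else 0L
  ms <- mean(vapply(raw, function(r) {
    core <- if (g > 0L) r[(g + 1L):(H - g), (g + 1L):(W - g)] else r
    mean(core^2)
  }, numeric(1)))
  lapply(raw, saturate_response, saturation = saturation, mean_square = ms)
}

# Elementwise max filter over a (2r+1)^2 window; out-of-frame treated as -Inf.
max_filter <- function(m, radius) {
  if (radius <= 0L) return(m)
  out <- m
  H <- nrow(m); W <- ncol(m)
  for (dr in -radius:radius) for (dc in -radius:radius) {
    if (dr == 0L && dc == 0L) next
    sh <- matrix(-Inf, H, W)
    rs <- seq_len(H) + dr; cs <- seq_len(W) + dc
    vr <- rs >= 1L & rs <= H; vc <- cs >= 1L & cs <= W
    sh[vr, vc] <- m[rs[vr], cs[vc], drop = FALSE]
    out <- pmax(out, sh)
  }
  out
}

# Pooled map for element type (oi, si): max over location shifts within
# bounds$location px and orientation steps within bounds$orientation (mod n).
pooled_map <- function(stack, dictionary, oi, si, bounds) {
  n <- dictionary$n_orientations
  oset <- unique(((oi - 1L + (-bounds$orientation:bounds$orientation)) %% n) + 1L)
  m <- NULL
  for (o in oset) {
    cur <- stack[[(si - 1L) * n + o]]
    m <- if (is.null(m)) cur else pmax(m, cur)
  }
  max_filter(m, bounds$location)
}

#' Perturbation bounds for active basis elements
#'
#' @param location maximum location shift in pixels (Chebyshev radius).
#' @param orientation maximum orientation shift in dictionary steps.
#' @export
abm_bounds <- function(location = 2L, orientation = 1L) {
  list(location = as.integer(location), orientation = as.integer(orientation))
}

#' Locally max-pooled response of one element placement
#'
#' Maximum saturated response over all allowed location/orientation
#' perturbations around the nominal placement, with the argmax placement.
#' Ties break deterministically: smallest row, then column, then orientation
#' index.
#'
#' @param stack saturated response maps (from all dictionary elements, as
#'   ordered in the dictionary) for one frame.
#' @param dictionary the `gabor_dictionary`.
#' @param center c(row, col), 1-based nominal center.
#' @param orientation_index,scale_index nominal element type.
#' @param bounds an [abm_bounds()] list.
#' @return list(value, row, col, orientation_index).
#' @export
local_max_pool <- function(stack, dictionary, center, orientation_index,
                           scale_index, bounds = abm_bounds()) {
  H <- nrow(stack[[1]]); W <- ncol(stack[[1]])
  n <- dictionary$n_orientations
  b <- bounds$location
  best <- list(value = -Inf, row = NA_integer_, col = NA_integer_,
               orientation_index = NA_integer_)
  for (dr in -b:b) {
    r <- center[1] + dr
    if (r < 1L || r > H) next
    for (dc in -b:b) {
      cc <- center[2] + dc
      if (cc < 1L || cc > W) next
      for (dori in -bounds$orientation:bounds$orientation) {
        o <- ((orientation_index - 1L + dori) %% n) + 1L
        v <- stack[[(scale_index - 1L) * n + o]][r, cc]
        if (v > best$value) best <- list(value = v, row = r, col = cc,
                                         orientation_index = o)
      }
    }
  }
  best
}

#' Train an active basis template by the shared sketch algorithm
#'
#' @param frames list of equal-shape training frames.
#' @param n_elements number of elements to select (>= 0).
#' @param dictionary a `gabor_dictionary`.
#' @param inhibition_radius suppression radius in pixels; placements within
#'   this Chebyshev radius whose orientation lies in the pooling neighborhood
#'   are suppressed after each selection. Default: half the kernel size at the
#'   selected element's scale.
#' @param bounds perturbation bounds used for pooling during selection.
#' @param saturation sigmoid saturation level.
#' @param roi optional logical matrix restricting element centers (the motion
#'   guidance hook).
#' @return an `abm_template`.
#' @export
train_shared_sketch <- function(frames, n_elements, dictionary,
                                inhibition_radius = NULL,
                                bounds = abm_bounds(), saturation = 6,
                                roi = NULL) {
  if (length(frames) == 0L) stop("empty training set", call. = FALSE)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all frames must share one shape", call. = FALSE)
  H <- dims[1, 1]; W <- dims[2, 1]
  n <- dictionary$n_orientations; m <- dictionary$n_scales
  stacks <- lapply(frames, abm_response_stack, dictionary = dictionary,
                   saturation = saturation)
  # Selection score per type: sum over frames of location-pooled maps.
  # Orientation pooling is deliberately left to match time: pooling over
  # neighboring orientations during selection makes adjacent nominal
  # orientations tie exactly at the response maximum, so the selected nominal
  # orientation would be arbitrary.
  sel_bounds <- abm_bounds(bounds$location, 0L)
  score <- vector("list", n * m)
  for (si in seq_len(m)) for (oi in seq_len(n)) {
    idx <- (si - 1L) * n + oi
    acc <- matrix(0, H, W)
    for (st in stacks) acc <- acc + pooled_map(st, dictionary, oi, si, sel_bounds)
    score[[idx]] <- acc
  }
  allowed <- if (is.null(roi)) matrix(TRUE, H, W) else roi
  for (si in seq_len(m)) {
    g <- (dictionary$kernel_sizes[si] - 1L) %/% 2L  # keep centers interior
    ok <- matrix(FALSE, H, W)
    if (H > 2L * g && W > 2L * g)
      ok[(g + 1L):(H - g), (g + 1L):(W - g)] <- TRUE
    for (oi in seq_len(n)) {
      idx <- (si - 1L) * n + oi
      score[[idx]][!(allowed & ok)] <- -Inf
    }
  }

  elements <- list(); weights <- numeric(0); gains <- numeric(0)
  for (step in seq_len(max(0L, n_elements))) {
    best <- list(value = -Inf)
    for (si in seq_len(m)) for (oi in seq_len(n)) {
      sc <- score[[(si - 1L) * n + oi]]
      v <- max(sc)
      if (v > best$value) {
        pos <- which(sc == v, arr.ind = TRUE)
        pos <- pos[order(pos[, 1], pos[, 2]), , drop = FALSE][1, ]
        best <- list(value = v, row = unname(pos[1]), col = unname(pos[2]),
                     orientation_index = oi, scale_index = si)
      }
    }
    if (!is.finite(best$value) || best$value <= 0) {
      warning(sprintf("only %d of %d elements selectable", step - 1L,
                      n_elements), call. = FALSE)
      break
    }
    rad <- if (is.null(inhibition_radius))
      (dictionary$kernel_sizes[best$scale_index] - 1L) %/% 2L
    else as.integer(inhibition_radius)
    el <- dict_element(dictionary, best$orientation_index, best$scale_index)
    elements[[length(elements) + 1L]] <- list(
      row = best$row, col = best$col,
      orientation_index = best$orientation_index,
      scale_index = best$scale_index,
      orientation = el$orientation, inhibition_radius = rad)
    gains <- c(gains, best$value)
    weights <- c(weights, best$value / length(frames))
    # suppress nearby placements of nearby orientations, all scales
    rs <- max(1L, best$row - rad):min(H, best$row + rad)
    cs <- max(1L, best$col - rad):min(W, best$col + rad)
    osup <- unique(((best$orientation_index - 1L +
                       (-bounds$orientation:bounds$orientation)) %% n) + 1L)
    for (si in seq_len(m)) for (o in osup)
      score[[(si - 1L) * n + o]][rs, cs] <- -Inf
  }

  # background response pool (outside selected inhibition regions) for the
  # per-element log normalizers log Phi(delta) = log E_bg[exp(delta * h)]
  bgmask <- matrix(TRUE, H, W)
  for (e in elements) {
    rs <- max(1L, e$row - e$inhibition_radius):min(H, e$row + e$inhibition_radius)
    cs <- max(1L, e$col - e$inhibition_radius):min(W, e$col + e$inhibition_radius)
    bgmask[rs, cs] <- FALSE
  }
  if (!any(bgmask)) bgmask[] <- TRUE
  bg <- unlist(lapply(stacks, function(st)
    lapply(st, function(mp) mp[bgmask])), use.names = FALSE)
  if (length(bg) > 20000L)
    bg <- bg[round(seq(1L, length(bg), length.out = 20000L))]
  log_normalizers <- vapply(weights, function(d) {
    mx <- d * max(bg)
    mx + log(mean(exp(d * bg - mx)))
  }, numeric(1))
  if (length(log_normalizers) == 0L) log_normalizers <- numeric(0)

  structure(list(elements = elements, weights = weights,
                 log_normalizers = log_normalizers,
                 selection_gains = gains,
                 n_elements = length(elements),
                 bounds = bounds, saturation = saturation,
                 frame_shape = c(H, W),
                 dict_params = list(n_orientations = dictionary$n_orientations,
                                    n_scales = dictionary$n_scales,
                                    base_size = dictionary$base_size,
                                    omega0 = dictionary$omega0,
                                    scale_step = dictionary$scale_step,
                                    gamma = dictionary$gamma)),
            class = "abm_template")
}

#' Match an active basis template against a frame
#'
#' Scores every translation of the template over the frame lattice:
#' score(shift) = sum_i delta_i * pooled response of element i at its shifted
#' nominal placement, minus the cached log normalizers; returns the maximum
#' and its shift. Ties break at the smallest row shift, then column shift.
#'
#' @param frame grayscale frame (matrix).
#' @param template an `abm_template`.
#' @param dictionary the dictionary the template was trained with (rebuilt
#'   from `template$dict_params` when omitted).
#' @param roi optional logical matrix: only shifts whose shifted template
#'   centroid falls in the ROI are considered (ignored when the ROI covers no
#'   candidate shift).
#' @return an `abm_match`: list(score, location = c(dr, dc) shift in px,
#'   per_element_responses, degenerate).
#' @export
match_template <- function(frame, template, dictionary = NULL, roi = NULL) {
  stopifnot(inherits(template, "abm_template"))
  if (template$n_elements == 0L)
    return(structure(list(score = 0, location = c(0L, 0L),
                          per_element_responses = numeric(0),
                          degenerate = TRUE), class = "abm_match"))
  if (is.null(dictionary))
    dictionary <- do.call(build_gabor_dictionary, template$dict_params)
  H <- nrow(frame); W <- ncol(frame)
  stack <- abm_response_stack(frame, dictionary, template$saturation)
  rows <- vapply(template$elements, `[[`, integer(1) + 0, "row")
  cols <- vapply(template$elements, `[[`, integer(1) + 0, "col")
  # allowed shifts keep every element center on the lattice
  lo_r <- 1L - min(rows); hi_r <- H - max(rows)
  lo_c <- 1L - min(cols); hi_c <- W - max(cols)
  if (lo_r > hi_r || lo_c > hi_c)
    stop("frame too small for template extent", call. = FALSE)
  nr <- hi_r - lo_r + 1L; nc <- hi_c - lo_c + 1L
  acc <- matrix(-sum(template$log_normalizers), nr, nc)
  pmaps <- vector("list", template$n_elements)
  for (i in seq_len(template$n_elements)) {
    e <- template$elements[[i]]
    pm <- pooled_map(stack, dictionary, e$orientation_index, e$scale_index,
                     template$bounds)
    pmaps[[i]] <- pm
    acc <- acc + template$weights[i] *
      pm[(e$row + lo_r):(e$row + hi_r), (e$col + lo_c):(e$col + hi_c),
         drop = FALSE]
  }
  sel <- matrix(TRUE, nr, nc)
  if (!is.null(roi)) {
    cen_r <- round(mean(rows)); cen_c <- round(mean(cols))
    rr <- clamp((cen_r + lo_r):(cen_r + hi_r), 1L, H)
    cc <- clamp((cen_c + lo_c):(cen_c + hi_c), 1L, W)
    roi_sel <- roi[rr, cc, drop = FALSE]
    if (any(roi_sel)) sel <- roi_sel
  }
  accs <- ifelse(sel, acc, -Inf)
  v <- max(accs)
  pos <- which(accs == v, arr.ind = TRUE)
  pos <- pos[order(pos[, 1], pos[, 2]), , drop = FALSE][1, ]
  shift <- unname(c(pos[1] - 1L + lo_r, pos[2] - 1L + lo_c))
  per <- vapply(seq_len(template$n_elements), function(i) {
    e <- template$elements[[i]]
    pmaps[[i]][e$row + shift[1], e$col + shift[2]]
  }, numeric(1))
  structure(list(score = v, location = as.integer(shift),
                 per_element_responses = per, degenerate = FALSE),
            class = "abm_match")
}

#' Serialize / deserialize an active basis template
#'
#' Versioned container: plain-text header (dictionary parameters, element
#' tuples with 0-based centers) followed by a little-endian float64 binary
#' payload (weights, log normalizers, selection gains). Round-trips exactly.
#'
#' @param template an `abm_template`.
#' @param path file path.
#' @export
write_template <- function(template, path) {
  stopifnot(inherits(template, "abm_template"))
  con <- file(path, "wb")
  on.exit(close(con))
  dp <- template$dict_params
  hdr <- c("BIOMOTION_TEMPLATE v1",
           sprintf("frame_shape %d %d", template$frame_shape[1],
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
                     e$orientation_index, e$scale_index,
                     e$inhibition_radius), character(1)),
           sprintf("payload %d", 3L * template$n_elements))
  writeLines(hdr, con)
  writeBin(as.numeric(c(template$weights, template$log_normalizers,
                        template$selection_gains)),
           con, size = 8L, endian = "little")
  invisible(path)
}

#' @rdname write_template
#' @export
read_template <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rdline <- function() {
    chars <- raw(0)
    repeat {
      b <- readBin(con, "raw", 1L)
      if (length(b) == 0L || b == as.raw(10L)) break
      chars <- c(chars, b)
    }
    rawToChar(chars)
  }
  stopifnot(rdline() == "BIOMOTION_TEMPLATE v1")
  fs <- as.integer(strsplit(rdline(), " ")[[1]][2:3])
  dv <- strsplit(rdline(), " ")[[1]][-1]
  dp <- list(n_orientations = as.integer(dv[1]), n_scales = as.integer(dv[2]),
             base_size = as.integer(dv[3]), omega0 = as.numeric(dv[4]),
             scale_step = as.numeric(dv[5]), gamma = as.numeric(dv[6]))
  sat <- as.numeric(strsplit(rdline(), " ")[[1]][2])
  bv <- as.integer(strsplit(rdline(), " ")[[1]][2:3])
  k <- as.integer(strsplit(rdline(), " ")[[1]][2])
  dict <- do.call(build_gabor_dictionary, dp)
  elements <- vector("list", k)
  for (i in seq_len(k)) {
    ev <- as.integer(strsplit(rdline(), " ")[[1]][-1])
    el <- dict_element(dict, ev[3], ev[4])
    elements[[i]] <- list(row = ev[1] + 1L, col = ev[2] + 1L,
                          orientation_index = ev[3], scale_index = ev[4],
                          orientation = el$orientation,
                          inhibition_radius = ev[5])
  }
  np <- as.integer(strsplit(rdline(), " ")[[1]][2])
  payload <- readBin(con, "numeric", np, size = 8L, endian = "little")
  w <- payload[seq_len(k)]
  ln <- payload[k + seq_len(k)]
  g <- payload[2L * k + seq_len(k)]
  structure(list(elements = elements, weights = w, log_normalizers = ln,
                 selection_gains = g, n_elements = k,
                 bounds = abm_bounds(bv[1], bv[2]), saturation = sat,
                 frame_shape = fs, dict_params = dp),
            class = "abm_template")
}
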