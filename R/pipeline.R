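#' End-to-end action recognition pipeline
#'
#' Training builds, per action class, a sparse active basis template (with the
#' shared sketch algorithm guided by a motion ROI) and a set of melted action
#' prototypes (two-stage synergetic melting across subjects and snippets).
#' Classification walks a sequence in temporal order: per frame it estimates
#' flow from the previous frame, updates the fuzzy flow-division state, gates
#' the candidate classes by dominant limb group, scores the gated classes'
#' order parameters, and finally takes a sequence label by majority vote.
#'
#' @name pipeline
NULL

#' The canonical six action classes and their limb groups
#'
#' @return named character vector mapping class name to "upper"/"lower".
#' @export
kth_class_groups <- function() {
  c(boxing = "upper", clapping = "upper", waving = "upper",
    walking = "lower", jogging = "lower", running = "lower")
}

#' Select frames from a sequence in temporal order
#'
#' Evenly strided subset from the start, never reordered (shuffling frames
#' destroys the biological perception of movement).
#'
#' @param sequence list of frames (or any vector-like of length n).
#' @param count number of frames to take (>= 3).
#' @param stride frame step; NULL picks the largest stride that fits.
#' @return integer vector of selected 1-based indices, strictly increasing.
#' @export
select_frames <- function(sequence, count = 3L, stride = NULL) {
  n <- length(sequence)
  count <- as.integer(count)
  if (count < 3L) stop("count must be >= 3", call. = FALSE)
  if (n < count) stop("sequence too short: ", n, " < ", count, call. = FALSE)
  if (is.null(stride)) stride <- max(1L, (n - 1L) %/% (count - 1L))
  stride <- as.integer(stride)
  idx <- 1L + (seq_len(count) - 1L) * stride
  if (idx[count] > n)
    stop("stride ", stride, " with count ", count,
         " exceeds sequence length ", n, call. = FALSE)
  idx
}

# ROI from a speed map: bounding box of pixels above the given quantile,
# dilated by `dilate` pixels.
flow_roi <- function(speed, quantile = 0.9, dilate = 4L) {
  H <- nrow(speed); W <- ncol(speed)
  thr <- stats::quantile(speed, quantile, names = FALSE)
  hot <- speed >= thr & speed > 0
  if (!any(hot)) return(matrix(TRUE, H, W))
  pos <- which(hot, arr.ind = TRUE)
  r1 <- max(1L, min(pos[, 1]) - dilate); r2 <- min(H, max(pos[, 1]) + dilate)
  c1 <- max(1L, min(pos[, 2]) - dilate); c2 <- min(W, max(pos[, 2]) + dilate)
  roi <- matrix(FALSE, H, W)
  roi[r1:r2, c1:c2] <- TRUE
  roi
}

# Evenly spaced snippet indices (always includes the first frame).
snippet_indices <- function(n, n_snippets) {
  if (n < n_snippets) stop("sequence shorter than snippet count", call. = FALSE)
  unique(round(seq(1L, n, length.out = n_snippets)))
}

#' Train a model from a training map
#'
#' @param training_map named list: action class -> list of subject sequences,
#'   each a list of equal-shape frames.
#' @param config configuration from [biomotion_config()].
#' @param class_groups named limb-group map covering all classes in the map;
#'   defaults to the canonical six-class grouping for known names.
#' @return a `biomotion_model`: per-class ABM templates, a prototype bank
#'   (MPOD class adjoint over retained prototypes), the limb-group map and
#'   the configuration.
#' @export
train_model <- function(training_map, config = biomotion_config(),
                        class_groups = NULL) {
  if (!is.list(training_map) || is.null(names(training_map)) ||
      any(!nzchar(names(training_map))))
    stop("training_map must be a named list: action -> subject sequences",
         call. = FALSE)
  if (is.null(class_groups)) {
    known <- kth_class_groups()
    if (!all(names(training_map) %in% names(known)))
      stop("unknown action classes: pass class_groups explicitly for ",
           paste(setdiff(names(training_map), names(known)), collapse = ", "),
           call. = FALSE)
    class_groups <- known[names(training_map)]
  }
  dict <- do.call(build_gabor_dictionary, config$gabor)
  fpar <- do.call(flow_params, config$flow)
  bounds <- abm_bounds(config$abm$bound_location, config$abm$bound_orientation)
  n_snip <- config$pipeline$n_snippets

  templates <- list()
  proto_cols <- list(); proto_labels <- character(0)
  for (cl in names(training_map)) {
    sequences <- training_map[[cl]]
    if (length(sequences) == 0L)
      stop("class '", cl, "': no subject sequences", call. = FALSE)
    if (isTRUE(config$pipeline$mirror_augment)) {
      sequences <- c(sequences,
                     lapply(sequences, function(sq) lapply(sq, mirror_horizontal)))
    }
    # snippet frames + union flow ROI per class
    snippet_frames <- vector("list", n_snip)  # snippet -> subject frames
    all_frames <- list()
    roi_union <- NULL
    for (sq in sequences) {
      idx <- snippet_indices(length(sq), n_snip)
      for (s in seq_along(idx)) {
        i <- idx[s]
        prev <- if (i > 1L) sq[[i - 1L]] else sq[[min(i + 1L, length(sq))]]
        fl <- estimate_flow(prev, sq[[i]], fpar)
        roi <- flow_roi(flow_speed(fl$forward), config$pipeline$roi_quantile,
                        config$pipeline$roi_dilate)
        roi_union <- if (is.null(roi_union)) roi else roi_union | roi
        snippet_frames[[s]] <- c(snippet_frames[[s]], list(sq[[i]]))
        all_frames <- c(all_frames, list(sq[[i]]))
      }
    }
    ir <- config$abm$inhibition_radius
    templates[[cl]] <- train_shared_sketch(
      all_frames, config$abm$n_elements, dict,
      inhibition_radius = if (is.na(ir)) NULL else ir,
      bounds = bounds, saturation = config$abm$saturation, roi = roi_union)
    protos <- build_action_prototypes(
      stats::setNames(list(snippet_frames), cl),
      P1 = config$snn$P1, P2 = config$snn$P2)[[cl]]
    cols <- if (identical(config$snn$prototype_mode, "final")) list(protos$F)
    else c(protos$P, list(protos$F))
    proto_cols <- c(proto_cols, cols)
    proto_labels <- c(proto_labels, rep(cl, length(cols)))
  }
  bank <- prototype_bank(do.call(cbind, proto_cols), proto_labels,
                         penalty = list(P1 = config$snn$P1,
                                        P2 = config$snn$P2))
  structure(list(class_groups = class_groups, templates = templates,
                 bank = bank, config = config),
            class = "biomotion_model")
}

#' Classify an image sequence
#'
#' For every selected frame after the first: estimate bidirectional flow from
#' the previous selected frame, update the fuzzy membership state, gate the
#' candidate classes by dominant limb group, evaluate order parameters of the
#' gated classes on the normalized frame (and, when enabled, the ABM match for
#' localization), and predict the best gated class. The sequence label is the
#' majority vote over per-frame predictions; vote ties break by summed order
#' parameters.
#'
#' @param frames list of >= 3 equal-shape frames.
#' @param model a `biomotion_model`.
#' @param config optional configuration overriding the model's.
#' @return a `sequence_result`: per_frame records (frame index, gate set,
#'   per-class scores, prediction, membership trace), final_label,
#'   vote_margin.
#' @export
classify_sequence <- function(frames, model, config = NULL) {
  stopifnot(inherits(model, "biomotion_model"))
  if (is.null(config)) config <- model$config
  if (length(frames) < config$pipeline$min_frames)
    stop("need at least ", config$pipeline$min_frames, " frames",
         call. = FALSE)
  shp <- model$templates[[1]]$frame_shape
  if (!all(dim(frames[[1]]) == shp))
    stop("frame shape ", paste(dim(frames[[1]]), collapse = "x"),
         " does not match model frame shape ", paste(shp, collapse = "x"),
         call. = FALSE)
  classes <- names(model$class_groups)
  dict <- do.call(build_gabor_dictionary, as.list(model$config$gabor))
  fpar <- do.call(flow_params, as.list(config$flow))
  division <- flow_division(shp)
  state <- membership_state(tau = config$fuzzy$tau, beta = config$fuzzy$beta,
                            beta_prime = config$fuzzy$beta_prime,
                            N = config$fuzzy$N)
  idx <- select_frames(frames, count = length(frames), stride = 1L)
  per_frame <- list()
  votes <- character(0)
  score_sum <- stats::setNames(numeric(length(classes)), classes)
  for (t in idx[-1]) {
    fl <- estimate_flow(frames[[t - 1L]], frames[[t]], fpar)
    cm <- cell_memberships(fl$forward, division)
    state <- temporal_update(state, cm)
    sc <- limb_scores(state, isTRUE(config$fuzzy$enable_left_right))
    gate <- if (isTRUE(config$pipeline$gate_enabled))
      gate_actions(sc, model$class_groups, config$fuzzy$margin)
    else classes
    q <- normalize_sample(frames[[t]])
    op <- order_parameters(q, model$bank)
    eps_gated <- op$eps[names(op$eps) %in% gate]
    pred <- names(eps_gated)[which.max(eps_gated)]
    abm_loc <- NULL
    if (isTRUE(config$pipeline$use_abm)) {
      roi <- flow_roi(flow_speed(fl$forward), config$pipeline$roi_quantile,
                      config$pipeline$roi_dilate)
      abm_loc <- match_template(frames[[t]], model$templates[[pred]], dict,
                                roi = roi)$location
    }
    votes <- c(votes, pred)
    score_sum[names(eps_gated)] <- score_sum[names(eps_gated)] + eps_gated
    per_frame[[length(per_frame) + 1L]] <- list(
      frame = t, gate = gate, eps = op$eps, prediction = pred,
      abm_location = abm_loc, mu_tilde = state$mu_tilde, k = state$k,
      winner = state$winner, mu_upper = sc$mu_upper, mu_lower = sc$mu_lower)
  }
  tab <- table(votes)
  top <- max(tab)
  tied <- names(tab)[tab == top]
  final <- if (length(tied) == 1L) tied
  else tied[which.max(score_sum[tied])]
  structure(list(per_frame = per_frame, final_label = final,
                 vote_margin = top / length(votes)),
            class = "sequence_result")
}

#' Write the per-frame membership trace as CSV
#'
#' @param result a `sequence_result`.
#' @param path CSV path.
#' @return the trace data.frame, invisibly writing it when `path` is given.
#' @export
membership_trace <- function(result, path = NULL) {
  stopifnot(inherits(result, "sequence_result"))
  rows <- lapply(result$per_frame, function(pf) {
    data.frame(frame = pf$frame, mu_C1 = pf$mu_tilde[["C1"]],
               mu_C2 = pf$mu_tilde[["C2"]], mu_C3 = pf$mu_tilde[["C3"]],
               mu_C4 = pf$mu_tilde[["C4"]],
               winner = ifelse(is.na(pf$winner), "none",
                               paste0("C", pf$winner)),
               k = pf$k, mu_upper = pf$mu_upper, mu_lower = pf$mu_lower,
               gate = paste(pf$gate, collapse = "|"),
               prediction = pf$prediction)
  })
  df <- do.call(rbind, rows)
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Evaluate a model on a labeled dataset
#'
#' @param model a `biomotion_model`.
#' @param dataset output of [gen_action_dataset()] (or a list with
#'   `sequences`, each carrying `frames` and `class`).
#' @param config optional configuration override.
#' @return list(accuracy, n, predictions, truth).
#' @export
evaluate_model <- function(model, dataset, config = NULL) {
  preds <- character(0); truth <- character(0)
  for (s in dataset$sequences) {
    r <- classify_sequence(s$frames, model, config)
    preds <- c(preds, r$final_label)
    truth <- c(truth, s$class)
  }
  list(accuracy = mean(preds == truth), n = length(truth),
       predictions = preds, truth = truth)
}
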