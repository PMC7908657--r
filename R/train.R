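#' Training configuration
#'
#' The reference profile matches the published training regime: Adam with an
#' initial learning rate of 0.5e-5, later dropped to 1e-7 (here: at 90% of
#' iterations, configurable), 60,000 iterations, and sampled augmentation
#' realizing a more-than-100-fold expansion of the data. The test profile
#' keeps the same machinery but scales everything to what a CPU smoke run
#' can afford (short schedule, higher learning rate so the tiny network
#' converges within the shortened budget).
#'
#' @param profile "reference" or "test".
#' @param lr_initial,lr_final Adam learning rates before/after the switch.
#' @param lr_switch fraction of iterations after which lr_final applies.
#' @param iterations number of optimisation steps (each consuming
#'   \code{batch_size} windows).
#' @param augmentation_multiplier nominal data-expansion factor; realized by
#'   sampling fresh draws, not materialization.
#' @param negative_ratio background windows sampled per positive window.
#'   Negative locations are mildly hardness-mined: a few uniform candidates
#'   are drawn and the brightest center slice wins, so background windows
#'   tend to contain normal cells rather than empty background.
#' @param clip_norm global gradient-norm clip (stabilises the focal loss's
#'   occasional large gradients); Inf disables. The default only touches
#'   rare spikes (typical early-training norms are 10-30).
#' @param batch_size windows per optimisation step (gradients averaged);
#'   batch composition is not pinned down by the published regime, so it is
#'   exposed here.
#' @param head_lr_mult learning-rate multiplier for the detection-head
#'   parameters; short schedules benefit from faster regression-branch
#'   convergence (the L1 losses have constant-magnitude gradients).
#' @param crop_size optional square training-crop size (multiple of 32):
#'   windows are cropped around the sampled location — biased to contain
#'   the annotated boxes for positive windows — before the forward pass,
#'   cutting per-iteration cost; NULL trains on full frames. Inference is
#'   fully convolutional and unaffected.
#' @param log_every record the running loss every this many iterations.
#' @param seed RNG seed for sampling and augmentation draws.
#' @return a \code{train_config} list.
#' @export
train_config <- function(profile = c("reference", "test"),
                         lr_initial = NULL, lr_final = NULL,
                         lr_switch = 0.9, iterations = NULL,
                         augmentation_multiplier = 100,
                         batch_size = 1L, negative_ratio = 1.0,
                         clip_norm = 25, crop_size = NULL, head_lr_mult = 1,
                         log_every = 25L, seed = 1L) {
  profile <- match.arg(profile)
  defaults <- if (profile == "reference") {
    list(lr_initial = 0.5e-5, lr_final = 1e-7, iterations = 60000L)
  } else {
    list(lr_initial = 1e-3, lr_final = 1e-4, iterations = 700L)
  }
  lr_initial <- lr_initial %||% defaults$lr_initial
  lr_final <- lr_final %||% defaults$lr_final
  iterations <- as.integer(iterations %||% defaults$iterations)
  if (lr_final > lr_initial) stop("lr_final must be <= lr_initial")
  if (iterations <= 0) stop("iterations must be > 0")
  structure(list(profile = profile, lr_initial = lr_initial,
                 lr_final = lr_final, lr_switch = lr_switch,
                 iterations = iterations, batch_size = as.integer(batch_size),
                 augmentation_multiplier = augmentation_multiplier,
                 negative_ratio = negative_ratio, clip_norm = clip_norm,
                 crop_size = if (is.null(crop_size)) NULL else as.integer(crop_size),
                 head_lr_mult = head_lr_mult,
                 log_every = as.integer(log_every), seed = as.integer(seed)),
            class = "train_config")
}

# sampling locations: every annotated (scene, t, s) is a positive; negatives
# are uniform draws re-sampled until they miss the positive set
sample_locations <- function(scenes) {
  pos <- list()
  for (si in seq_along(scenes)) {
    ann <- scenes[[si]]$annotations
    if (nrow(ann) == 0) next
    u <- unique(ann[, c("t", "s")])
    for (r in seq_len(nrow(u)))
      pos[[length(pos) + 1]] <- c(scene = si, t = u$t[r], s = u$s[r])
  }
  pos
}

#' Train a detector on annotated volumes
#'
#' Minimises the detection loss over augmented temporal windows sampled
#' around annotated locations and around background locations (1:1 by
#' default; background windows mix border negatives near events with
#' bright uniform candidates). Gradients are averaged over
#' \code{batch_size} windows per Adam step; the learning rate switches
#' from \code{lr_initial} to \code{lr_final} at \code{lr_switch} of the
#' iterations. Training aborts with a diagnostic if the loss goes
#' non-finite.
#'
#' @param model a \code{mito_detector} (modified in place; also returned).
#' @param scenes list of scenes, each \code{list(volume, annotations)}.
#' @param config a \code{\link{train_config}}.
#' @param aug an \code{\link{augment_spec}} (identity transform if NULL).
#' @param verbose print the running loss at each log point.
#' @return a list with \code{model} and \code{log} (data frame of iteration,
#'   loss, learning rate).
#' @export
train_detector <- function(model, scenes, config = train_config("test"),
                           aug = augment_spec(), verbose = FALSE) {
  positives <- sample_locations(scenes)
  if (length(positives) == 0) stop("training needs at least one annotation")
  positive_keys <- vapply(positives, function(p)
    paste(p[["scene"]], p[["t"]], p[["s"]]), "")
  t_cfg <- model$config$temporal
  h_cfg <- model$config$head
  log <- data.frame(iteration = integer(), loss = numeric(), lr = numeric())
  run_loss <- NULL
  with_seed(config$seed, {
    p_pos <- 1 / (1 + config$negative_ratio)
    one_window <- function(it) {
      take_pos <- stats::runif(1) < p_pos
      anchor <- NULL
      if (take_pos) {
        loc <- positives[[sample.int(length(positives), 1)]]
      } else if (stats::runif(1) < 0.5) {
        # border negatives: windows offset a little from an annotated
        # location in time or z. The temporal window and the 2.5D stack
        # both carry event signal into these windows, so without explicit
        # examples the head leaks detections past the event's extent.
        loc <- NULL
        for (try in 1:20) {
          base <- positives[[sample.int(length(positives), 1)]]
          d <- dim(scenes[[base[["scene"]]]]$volume$data)
          tt <- base[["t"]] + sample(-3:3, 1)
          ss <- base[["s"]] + sample(-3:3, 1)
          if (tt < 0 || tt >= d[1] || ss < 0 || ss >= d[2]) next
          if (paste(base[["scene"]], tt, ss) %in% positive_keys) next
          loc <- c(scene = base[["scene"]], t = tt, s = ss)
          break
        }
        if (is.null(loc))
          loc <- positives[[sample.int(length(positives), 1)]]
        # crop around the event's location so the border window actually
        # contains the leaking signal
        bann <- scenes[[base[["scene"]]]]$annotations
        bann <- bann[bann$t == base[["t"]] & bann$s == base[["s"]], ,
                     drop = FALSE]
        if (nrow(bann) > 0) anchor <- c(mean(bann$cx), mean(bann$cy))
      } else {
        # mild hard-negative mining: of a few uniform candidates keep the
        # one whose center slice carries the most signal
        best <- NULL; best_q <- -Inf
        for (cand in 1:3) {
          si <- sample.int(length(scenes), 1)
          d <- dim(scenes[[si]]$volume$data)
          tt <- sample.int(d[1], 1) - 1L
          ss <- sample.int(d[2], 1) - 1L
          q <- stats::quantile(scenes[[si]]$volume$data[tt + 1, ss + 1, , ],
                               0.999)
          if (q > best_q) {
            best_q <- q
            best <- c(scene = si, t = tt, s = ss)
          }
        }
        loc <- best
      }
      scene <- scenes[[loc[["scene"]]]]
      win <- extract_window(scene$volume, loc[["t"]], loc[["s"]], t_cfg)
      ann <- scene$annotations
      ann <- ann[ann$t == loc[["t"]] & ann$s == loc[["s"]], , drop = FALSE]
      H <- dim(win$frames[[1]])[1]; W <- dim(win$frames[[1]])[2]
      if (!is.null(aug)) {
        draw <- augment_draw(aug, H, W)
        res <- lapply(win$frames, function(f) augment_apply(f, ann, draw))
        win$frames <- lapply(res, `[[`, "stack")
        ann <- res[[win$center]]$ann
        H <- dim(win$frames[[1]])[1]; W <- dim(win$frames[[1]])[2]
      }
      cs <- config$crop_size
      if (!is.null(cs) && cs < min(H, W)) {
        # keep the annotated boxes inside the crop when there are any
        cx0 <- if (nrow(ann) > 0) mean(ann$cx)
               else if (!is.null(anchor)) anchor[1]
               else stats::runif(1, 0, W)
        cy0 <- if (nrow(ann) > 0) mean(ann$cy)
               else if (!is.null(anchor)) anchor[2]
               else stats::runif(1, 0, H)
        # place the object uniformly within the crop (not centered): a
        # centered-object bias would let zero-padding position cues leak
        # into the learned score and size maps
        ox <- round(cx0 - stats::runif(1, 0.2, 0.8) * cs)
        oy <- round(cy0 - stats::runif(1, 0.2, 0.8) * cs)
        ox <- min(max(ox, 0), W - cs); oy <- min(max(oy, 0), H - cs)
        win$frames <- lapply(win$frames, function(f)
          f[oy + seq_len(cs), ox + seq_len(cs), , drop = FALSE])
        if (nrow(ann) > 0) {
          ann$cx <- ann$cx - ox
          ann$cy <- ann$cy - oy
          ann <- ann[ann$cx >= 0 & ann$cx < cs & ann$cy >= 0 & ann$cy < cs, ,
                     drop = FALSE]
        }
        H <- cs; W <- cs
      }
      target <- render_targets(ann, c(H %/% 4L, W %/% 4L), h_cfg)
      fwd <- detector_forward(model, win, grad = TRUE)
      loss <- detection_loss(fwd$tape, fwd$pred, target, h_cfg)
      if (!is.finite(loss$v))
        stop("non-finite loss at iteration ", it, " (scene ",
             loc[["scene"]], ", t=", loc[["t"]], ", s=", loc[["s"]], ")")
      list(loss = loss$v, pg = nn_backward(fwd$tape, loss))
    }
    for (it in seq_len(config$iterations)) {
      lr <- if (it <= config$lr_switch * config$iterations)
        config$lr_initial else config$lr_final
      # average gradients over the batch
      acc <- new.env(parent = emptyenv())
      loss_v <- 0
      for (b in seq_len(config$batch_size)) {
        r <- one_window(it)
        loss_v <- loss_v + r$loss / config$batch_size
        for (n in ls(r$pg)) {
          g <- r$pg[[n]] / config$batch_size
          if (is.null(acc[[n]])) acc[[n]] <- g else acc[[n]] <- acc[[n]] + g
        }
      }
      pg <- acc
      if (is.finite(config$clip_norm)) {
        gn <- sqrt(sum(vapply(ls(pg), function(n) sum(pg[[n]]^2), numeric(1))))
        if (gn > config$clip_norm) {
          sc <- config$clip_norm / gn
          for (n in ls(pg)) pg[[n]] <- pg[[n]] * sc
        }
      }
      adam_step(model$params, pg, lr,
                lr_mult = if (config$head_lr_mult != 1)
                  c(hd. = config$head_lr_mult) else NULL)
      run_loss <- if (is.null(run_loss)) loss_v else 0.95 * run_loss + 0.05 * loss_v
      if (it %% config$log_every == 0 || it == config$iterations) {
        log <- rbind(log, data.frame(iteration = it, loss = run_loss, lr = lr))
        if (verbose)
          message(sprintf("iter %5d  loss %.4f  lr %.2g", it, run_loss, lr))
      }
    }
  })
  list(model = model, log = log)
}

# pad a volume on the bottom/right (edge replication) so H and W divide 32
pad_volume <- function(volume, div = 32L) {
  d <- dim(volume$data)
  H2 <- as.integer(ceiling(d[3] / div) * div)
  W2 <- as.integer(ceiling(d[4] / div) * div)
  if (H2 == d[3] && W2 == d[4]) return(volume)
  data <- array(0, c(d[1], d[2], H2, W2))
  yi <- pmin(seq_len(H2), d[3]); xi <- pmin(seq_len(W2), d[4])
  for (t in seq_len(d[1])) for (s in seq_len(d[2]))
    data[t, s, , ] <- volume$data[t, s, yi, xi]
  structure(list(data = data, spec = volume$spec,
                 dims = c(t = d[1], s = d[2], y = H2, x = W2)),
            class = "mito_volume4d")
}

#' Run the detector over every (frame, slice) of a volume
#'
#' For each window center the backbone features of the overlapping 2.5D
#' stacks are computed once and cached (a stack is shared by up to seven
#' windows), then the temporal aggregation and head run per window and the
#' decoded boxes are stamped with (t, s). Volumes whose height/width do not
#' divide 32 are edge-padded on the bottom/right; boxes whose center falls
#' in the padding are dropped.
#'
#' @param volume a \code{mito_volume4d}.
#' @param model a trained \code{mito_detector}.
#' @param frames,slices optional 0-based subsets to restrict inference to.
#' @param verbose print a progress line per frame.
#' @return a box table of raw detections (pre-refinement).
#' @export
detect_volume <- function(volume, model, frames = NULL, slices = NULL,
                          verbose = FALSE) {
  d0 <- dim(volume$data)
  volume <- pad_volume(volume)
  d <- dim(volume$data)
  t_cfg <- model$config$temporal
  h_cfg <- model$config$head
  frames <- frames %||% (seq_len(d[1]) - 1L)
  slices <- slices %||% (seq_len(d[2]) - 1L)
  cache <- new.env(parent = emptyenv())
  get_maps <- function(tf, s) {
    key <- paste(tf, s, sep = ":")
    m <- cache[[key]]
    if (is.null(m)) {
      win1 <- extract_window(volume, tf, s,
                             temporal_config(1L, t_cfg$slice_span,
                                             t_cfg$hidden_per_scale,
                                             t_cfg$proj_channels))
      m <- detector_backbone_maps(model, win1$frames[[1]])
      cache[[key]] <- m
    }
    m
  }
  out <- list()
  ht <- t_cfg$temporal_span %/% 2L
  for (t in frames) {
    for (s in slices) {
      ts <- pmin(pmax((t - ht):(t + ht), 0L), d[1] - 1L)
      maps <- lapply(ts, get_maps, s = s)
      pred <- detector_head_from_maps(model, maps, ht + 1L)
      det <- decode_detections(pred, t, s, h_cfg)
      if (nrow(det) > 0) out[[length(out) + 1]] <- det
    }
    # stacks more than ht frames behind can no longer be needed
    stale <- ls(cache)
    tf <- as.integer(sub(":.*", "", stale))
    rm(list = stale[tf < t - ht], envir = cache)
    if (verbose) message("frame ", t, ": ",
                         sum(vapply(out, nrow, numeric(1))), " boxes so far")
  }
  det <- if (length(out) > 0) validate_boxes(do.call(rbind, out))
         else empty_boxes()
  inside <- det$cx < d0[4] & det$cy < d0[3]
  if (any(!inside)) det <- validate_boxes(det[inside, , drop = FALSE])
  rownames(det) <- NULL
  det
}

#' End-to-end pipeline on synthetic scenes
#'
#' Simulate -> train (test profile) -> detect -> refine -> evaluate, with a
#' machine-readable report. This is the programmatic equivalent of the
#' command-line \code{run-all} and the shape of the package's smoke test.
#'
#' @param train_specs,eval_specs lists of \code{\link{scene_spec}}s for the
#'   training and held-out scenes.
#' @param detector a \code{\link{detector_config}}.
#' @param train_cfg a \code{\link{train_config}}.
#' @param refine_cfg a \code{\link{refinement_config}}.
#' @param aug an \code{\link{augment_spec}} or NULL.
#' @param seed weight-initialisation seed.
#' @param verbose print progress.
#' @return a list with the trained \code{model}, per-scene detections
#'   (raw and refined), and 2D/4D evaluation reports before and after
#'   refinement.
#' @export
run_pipeline <- function(train_specs, eval_specs,
                         detector = detector_config(),
                         train_cfg = train_config("test"),
                         refine_cfg = refinement_config(),
                         aug = augment_spec(), seed = 1L, verbose = FALSE) {
  train_scenes <- lapply(train_specs, generate_scene)
  eval_scenes <- lapply(eval_specs, generate_scene)
  model <- detector_init(detector, seed = seed)
  fit <- train_detector(model, train_scenes, train_cfg, aug = aug,
                        verbose = verbose)
  model <- fit$model
  results <- lapply(eval_scenes, function(scene) {
    d <- dim(scene$volume$data)
    raw <- detect_volume(scene$volume, model, verbose = verbose)
    ref <- refine(raw, n_slices = d[2], n_frames = d[1], refine_cfg)
    list(annotations = scene$annotations, raw = raw, refined = ref,
         eval2d_raw = evaluate_2d(raw, scene$annotations),
         eval2d = evaluate_2d(ref, scene$annotations),
         eval4d = evaluate_4d(ref, scene$annotations))
  })
  list(model = model, log = fit$log, scenes = results)
}
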