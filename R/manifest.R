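#' Run manifests: reproducible experiment descriptions
#'
#' A run manifest captures everything needed to re-execute an experiment
#' bit-identically: the input (a frame directory path, or the full argument
#' list of the synthetic looming generator), an input content hash, the
#' network parameters, any input or layer noise, the trial count and the
#' master seed. Manifests serialize losslessly to JSON.
#'
#' @param input Either a path to a frame directory, or a named list of
#'   [looming_sequence()] arguments describing a synthetic input.
#' @param params An [lgmd_params()] object.
#' @param n Number of replicate trials.
#' @param seed Master seed.
#' @param input_noise Optional list: `kind` (`"salt_pepper"`/`"gaussian"`),
#'   `pnr` or `gnv`, and `seed`, applied to the input before the run.
#' @param layer_noise Optional intermediate-layer noise (see [lgmd()]).
#' @return An object of class `"lgmd_manifest"`.
#' @examples
#' m <- run_manifest(list(rows = 40, cols = 40, frames = 20, collision_frame = 18),
#'                   lgmd_params(prob = 0.5), n = 3, seed = 1)
#' ens <- rerun_manifest(m)
#' @export
run_manifest <- function(input, params = lgmd_params(), n = 20, seed = 1,
                         input_noise = NULL, layer_noise = NULL) {
  stopifnot(inherits(params, "lgmd_params"))
  spec <- if (is.character(input)) {
    list(type = "path", path = input)
  } else if (is.list(input)) {
    list(type = "looming", args = input)
  } else stop("'input' must be a directory path or a looming argument list")
  m <- structure(
    list(input = spec,
         input_hash = NULL,
         params = unclass(params)[c("np", "u", "WI", "Ts", "Cw", "prob")],
         n = n, seed = seed,
         input_noise = input_noise, layer_noise = layer_noise,
         package_version = as.character(utils::packageVersion("problgmd"))),
    class = "lgmd_manifest")
  m$input_hash <- hash_frames(manifest_frames(m))
  m
}

hash_frames <- function(frames) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(as.vector(unclass(frames)), con, version = 2)
  close(con)
  unname(tools::md5sum(f))
}

#' Reconstruct the input frame sequence described by a manifest
#' @param m An `"lgmd_manifest"`.
#' @return A [frame_sequence()] (with any input noise applied).
#' @rdname run_manifest
#' @export
manifest_frames <- function(m) {
  stopifnot(inherits(m, "lgmd_manifest"))
  frames <- if (m$input$type == "path") {
    load_frames(m$input$path)
  } else {
    do.call(looming_sequence, m$input$args)
  }
  if (!is.null(m$input_noise)) {
    ns <- m$input_noise
    frames <- switch(ns$kind,
      salt_pepper = add_salt_pepper(frames, ns$pnr, seed = ns$seed),
      gaussian = add_gaussian_noise(frames, ns$gnv, seed = ns$seed),
      stop("unknown input noise kind: ", ns$kind))
  }
  frames
}

#' Re-execute the experiment a manifest describes
#' @return For `rerun_manifest`, the resulting [run_trials()] ensemble.
#' @rdname run_manifest
#' @export
rerun_manifest <- function(m) {
  stopifnot(inherits(m, "lgmd_manifest"))
  frames <- manifest_frames(m)
  if (!identical(hash_frames(frames), m$input_hash))
    warning("input content hash differs from the manifest")
  params <- do.call(lgmd_params, m$params)
  run_trials(frames, params, n = m$n, seed = m$seed,
             layer_noise = m$layer_noise)
}

#' @rdname run_manifest
#' @param path File path for the JSON manifest.
#' @export
write_manifest <- function(m, path) {
  stopifnot(inherits(m, "lgmd_manifest"))
  jsonlite::write_json(unclass(m), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname run_manifest
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (m$input$type == "looming") m$input$args <- as.list(m$input$args)
  for (fld in c("input_noise", "layer_noise"))
    if (!is.null(m[[fld]])) m[[fld]] <- as.list(m[[fld]])
  structure(m, class = "lgmd_manifest")
}

#' @export
print.lgmd_manifest <- function(x, ...) {
  cat("LGMD run manifest\n")
  cat(sprintf("  input: %s (md5 %s)\n",
              if (x$input$type == "path") x$input$path else "synthetic looming",
              substr(x$input_hash, 1, 8)))
  cat(sprintf("  prob = %g, n = %d trials, seed = %d\n",
              x$params$prob, x$n, x$seed))
  invisible(x)
}

#' Write a response trace or ensemble as CSV
#'
#' For a single `"lgmd"` run: columns `frame`, `K`, `kappa`. For an
#' `"lgmd_ensemble"`: columns `frame`, `kappa_mean`, `kappa_var`, then one
#' `trial_k` column per replicate.
#'
#' @param x An `"lgmd"` or `"lgmd_ensemble"` object.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_trace_csv <- function(x, path) {
  df <- if (inherits(x, "lgmd_ensemble")) {
    tr <- x$traces
    colnames(tr) <- sprintf("trial_%d", seq_len(ncol(tr)))
    data.frame(frame = seq_len(nrow(tr)), kappa_mean = x$mean,
               kappa_var = x$var, tr)
  } else if (inherits(x, "lgmd")) {
    as.data.frame(x)
  } else stop("'x' must be an lgmd run or ensemble")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
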