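#' Read and write canonical session files
#'
#' Sessions are persisted as plain CSV in the canonical schema
#' (`participant_id`, `trial`, `d1..dN`, `nu`, and any of `y`, `c`, `delta`,
#' `block`, `block_c`, `block_delta`), with an optional JSON sidecar
#' (`<path>.json`) holding the generator configuration.
#'
#' @param session Session (or cohort) tibble.
#' @param path CSV file path.
#' @param sidecar Write the generator-config JSON sidecar if present.
#' @export
write_session <- function(session, path, sidecar = TRUE) {
  utils::write.csv(session, path, row.names = FALSE)
  cfg <- attr(session, "generator_config")
  if (sidecar && !is.null(cfg)) {
    jsonlite::write_json(unclass(cfg), paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  out <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    cfg <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    attr(out, "generator_config") <- structure(cfg, class = "generator_config")
  }
  out
}

#' Read and write cohort ground-truth manifests
#'
#' The manifest records, for every simulated participant, the generating
#' model, its true parameters and the seed — everything recovery scoring
#' needs. Serialized as JSON, round-tripping exactly.
#'
#' @param manifest Manifest tibble from [simulate_cohort()].
#' @param path JSON file path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(
    purrr::map(seq_len(nrow(manifest)), function(i)
      list(participant_id = manifest$participant_id[i],
           model_id = manifest$model_id[i],
           seed = manifest$seed[i],
           params = manifest$params[[i]])),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  tibble(
    participant_id = purrr::map_chr(raw, "participant_id"),
    model_id = purrr::map_chr(raw, "model_id"),
    seed = purrr::map_int(raw, ~ as.integer(.x$seed)),
    params = purrr::map(raw, function(r)
      purrr::map(r$params, ~ if (length(.x) > 1) as.numeric(.x)
                 else as.numeric(.x[[1]]))))
}

#' Import a MATLAB session container
#'
#' Maps the arrays of a MATLAB data file into the canonical session schema.
#' No MATLAB reader is available to R directly, so this bridges through a
#' system `python` with `scipy.io`; it fails loudly if python/scipy is
#' unavailable or the file's layout is not recognized. Recognized layouts
#' are struct fields (case-insensitive) `d`/`samples`/`stimuli` (trials x 4),
#' `y`/`responses` (trials), and optionally `nu`.
#'
#' @param path Path to the `.mat` file.
#' @param participant_id Identifier to assign.
#' @return A canonical session tibble.
#' @export
import_mat_session <- function(path, participant_id = "imported") {
  if (!file.exists(path)) abort(paste0("MAT file not found: ", path))
  python <- Sys.which("python")
  if (python == "") abort("no `python` on PATH; cannot read MATLAB containers")
  tmp <- tempfile(fileext = ".csv")
  script <- paste0(
    "import sys, csv\n",
    "try:\n",
    "    from scipy.io import loadmat\n",
    "except Exception:\n",
    "    sys.exit('scipy is required to read MATLAB containers')\n",
    "m = loadmat(sys.argv[1], squeeze_me=True)\n",
    "keys = {k.lower(): k for k in m if not k.startswith('__')}\n",
    "dk = next((keys[k] for k in ('d','samples','stimuli') if k in keys), None)\n",
    "yk = next((keys[k] for k in ('y','responses','resp') if k in keys), None)\n",
    "if dk is None or yk is None:\n",
    "    sys.exit('unrecognized MAT layout; fields: ' + ','.join(keys))\n",
    "import numpy as np\n",
    "d = np.atleast_2d(np.asarray(m[dk], dtype=float))\n",
    "y = np.asarray(m[yk], dtype=float).ravel()\n",
    "if d.shape[0] != y.size: d = d.T\n",
    "if d.shape[0] != y.size or d.shape[1] != 4:\n",
    "    sys.exit('unrecognized MAT layout: d is %s, y has %d' % (d.shape, y.size))\n",
    "nu = np.asarray(m[keys['nu']], dtype=float).ravel() if 'nu' in keys else np.sqrt((d**2).mean(axis=1))\n",
    "w = csv.writer(open(sys.argv[2], 'w'))\n",
    "w.writerow(['trial','d1','d2','d3','d4','nu','y'])\n",
    "for t in range(y.size):\n",
    "    w.writerow([t+1] + list(d[t]) + [nu[t], y[t]])\n")
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  status <- suppressWarnings(system2(python, c(sf, shQuote(path), shQuote(tmp)),
                                     stdout = TRUE, stderr = TRUE))
  if (!file.exists(tmp) || length(attr(status, "status")) > 0) {
    abort(paste0("MAT import failed: ",
                 paste(status, collapse = " ")))
  }
  out <- as_tibble(utils::read.csv(tmp))
  dplyr::bind_cols(tibble(participant_id = participant_id), out)
}

#' Write an evidence table to CSV
#'
#' @param evidence Tidy evidence tibble (`participant_id`, `model_id`,
#'   `cvll`).
#' @param path CSV path.
#' @export
write_evidence <- function(evidence, path) {
  utils::write.csv(evidence, path, row.names = FALSE)
  invisible(path)
}
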