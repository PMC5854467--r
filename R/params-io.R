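# Plain-text per-particle parameter tables in the classic refinement
# layout: one row per particle with Euler angles, shifts, magnification,
# defocus, occupancy, log-probability, noise sigma and score. Write ->
# read -> write round trips are byte-identical.

par_columns <- c("index", "psi", "theta", "phi", "sx", "sy", "mag",
                 "defocus1", "defocus2", "astig_angle", "phase_shift",
                 "occupancy", "logp", "sigma", "score")

#' Write a per-particle parameter table
#'
#' Columns: index, psi, theta, phi (degrees), sx, sy (Angstrom), mag,
#' defocus1, defocus2 (Angstrom), astig_angle (degrees), phase_shift
#' (radians), occupancy (percent), logp, sigma, score. A `#`-prefixed
#' header line names the columns.
#'
#' @param df data.frame with the columns above (missing ones filled with
#'   defaults)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_par <- function(df, path) {
  defaults <- list(mag = 1, defocus1 = 0, defocus2 = 0, astig_angle = 0,
                   phase_shift = 0, occupancy = 100, logp = 0, sigma = 1,
                   score = 0, sx = 0, sy = 0, psi = 0, theta = 0, phi = 0)
  for (cn in par_columns)
    if (is.null(df[[cn]])) df[[cn]] <- if (cn == "index")
      seq_len(nrow(df)) else defaults[[cn]]
  df <- df[par_columns]
  lines <- c(paste0("# ", paste(par_columns, collapse = " ")),
             vapply(seq_len(nrow(df)), function(i)
               paste0(sprintf("%d", as.integer(df$index[i])), " ",
                      paste(sprintf("%.6f", as.numeric(df[i, -1])),
                            collapse = " ")),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a per-particle parameter table
#'
#' @param path file written by [write_par()]
#' @return data.frame with the standard columns
#' @export
read_par <- function(path) {
  df <- read.table(path, header = FALSE, comment.char = "#",
                   col.names = par_columns)
  df$index <- as.integer(df$index)
  df
}

#' Convert a parameter table to a list of alignment parameters
#'
#' @param df data.frame from [read_par()]
#' @return list of `alignment_params`
#' @export
par_to_alignment <- function(df) {
  lapply(seq_len(nrow(df)), function(i)
    alignment_params(phi = df$phi[i], theta = df$theta[i], psi = df$psi[i],
                     sx = df$sx[i], sy = df$sy[i],
                     magnification = df$mag[i]))
}

#' Convert alignment parameters (plus metadata) to a parameter table
#'
#' @param params list of `alignment_params`
#' @param scores optional score vector
#' @param ctfs optional per-particle `ctf_params` (or shared)
#' @param sigma optional noise sigma vector
#' @param occupancy optional occupancy (percent) vector
#' @return data.frame in the standard layout
#' @export
alignment_to_par <- function(params, scores = NULL, ctfs = NULL,
                             sigma = NULL, occupancy = NULL) {
  n <- length(params)
  df <- data.frame(
    index = seq_len(n),
    psi = vapply(params, `[[`, numeric(1), "psi"),
    theta = vapply(params, `[[`, numeric(1), "theta"),
    phi = vapply(params, `[[`, numeric(1), "phi"),
    sx = vapply(params, `[[`, numeric(1), "sx"),
    sy = vapply(params, `[[`, numeric(1), "sy"),
    mag = vapply(params, `[[`, numeric(1), "magnification"))
  df$defocus1 <- df$defocus2 <- df$astig_angle <- df$phase_shift <- 0
  if (!is.null(ctfs)) {
    for (i in seq_len(n)) {
      ci <- ctf_of(ctfs, i)
      df$defocus1[i] <- ci$defocus1
      df$defocus2[i] <- ci$defocus2
      df$astig_angle[i] <- ci$astig_angle
      df$phase_shift[i] <- ci$phase_shift
    }
  }
  df$occupancy <- if (is.null(occupancy)) 100 else occupancy
  df$logp <- 0
  df$sigma <- if (is.null(sigma)) 1 else sigma
  df$score <- if (is.null(scores)) 0 else scores
  df
}
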