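# Shared fixtures, generated in code. Sizes are desk-scale so the whole
# suite stays in the minutes range.

fix_env <- new.env()

# memoize expensive fixtures within one test run
fixture <- function(name, expr) {
  if (!exists(name, envir = fix_env)) {
    assign(name, force(expr), envir = fix_env)
  }
  get(name, envir = fix_env)
}

small_phantom <- function(box = 32, px = 3) {
  fixture(sprintf("phantom_%d_%g", box, px), default_phantom(box, px))
}

# dumbbell phantom with two well-separated characteristic views
dumbbell_phantom <- function(box = 48, px = 3) {
  fixture("dumbbell", {
    blobs <- data.frame(x = c(0, 0), y = c(0, 0), z = c(-28, 28),
                        sigma = c(11, 11), amplitude = c(1, 1))
    make_phantom(blobs, box, px)
  })
}

base_ctf <- function(px = 3) {
  ctf_params(defocus1 = 15000, voltage = 300, cs = 2.7,
             amplitude_contrast = 0.07, pixel_size = px)
}

# two-state phantom: a satellite blob moves between two positions
two_state_phantoms <- function(box = 32, px = 3) {
  fixture("two_state", {
    base <- data.frame(x = c(0, 10, -12), y = c(0, 12, -6),
                       z = c(0, -8, 10), sigma = c(10, 5, 5),
                       amplitude = c(0.6, 0.9, 0.9))
    sat_a <- data.frame(x = 22, y = 0, z = 0, sigma = 5, amplitude = 1.2)
    sat_b <- data.frame(x = -6, y = -22, z = 6, sigma = 5, amplitude = 1.2)
    list(a = make_phantom(rbind(base, sat_a), box, px),
         b = make_phantom(rbind(base, sat_b), box, px),
         sat_a = c(22, 0, 0), sat_b = c(-6, -22, 6))
  })
}
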