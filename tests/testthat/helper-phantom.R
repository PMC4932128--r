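# Shared fixtures: kept tiny so each test file stays fast.

tiny_scene <- function(dim = c(16, 16, 16), ...) {
  default_phantom_scene(dim = dim, ...)
}

# Two-tissue rectangular phantom with hand-set GM/WM maps, used by PVC and
# ROI tests where full brain geometry would obscure the arithmetic.
slab_phantom <- function(d = c(20, 20, 20), gm_value = 1.4, wm_value = 1.0) {
  gm <- array(0, d); wm <- array(0, d)
  gm[4:9, 4:17, 4:17] <- 1
  wm[12:17, 4:17, 4:17] <- 1
  list(gm = gm, wm = wm, vol = gm_value * gm + wm_value * wm)
}
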