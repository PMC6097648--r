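# Internal helpers shared across modules.

## Round half away from zero; base round() rounds half-to-even, which is
## wrong for the deterministic pixel conversions used here (5/0.22 -> 23).
roundHalfUp <- function(x) trunc(x + 0.5 * sign(x))

## Congruence check used by every mask-consuming operation: identical array
## dimensions and identical voxel geometry.  Hard error, never broadcast.
stopIfIncongruent <- function(a, b, what = "operands") {
    da <- dim(a)
    db <- dim(b)
    if (!identical(da, db)) {
        stop(sprintf("incongruent %s: shape %s vs %s", what,
                     paste(da, collapse = "x"), paste(db, collapse = "x")),
             call. = FALSE)
    }
    ga <- geometry(a)
    gb <- geometry(b)
    if (!isTRUE(all.equal(c(ga@dx, ga@dy, ga@dz), c(gb@dx, gb@dy, gb@dz),
                          tolerance = 1e-6))) {
        stop(sprintf("incongruent %s: voxel geometry differs", what),
             call. = FALSE)
    }
    invisible(TRUE)
}

## The two in-plane axes given the anteroposterior axis; the mediolateral
## axis is the column axis (2) unless that is the AP axis, in which case
## rows (1) carry the mediolateral coordinate.
mlAxisFor <- function(apAxis) if (apAxis == 2L) 1L else 2L
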