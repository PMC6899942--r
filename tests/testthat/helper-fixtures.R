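# Shared fixtures, built in code. The phase table is cached package-wide,
# so the first file that needs it pays the Monte-Carlo build once.

phase_tbl <- function() default_phase_table()

# a rich two-shape, three-diffusion-time scheme for recovery tests
rich_scheme <- function() {
  acquisition_scheme(
    b = c(0, 0, 10, 20, 40, 80, 150, 300, 450, 600,
          0, 10, 20, 40, 60, 100, 150, 175,
          10, 30, 60, 100, 150,
          20, 50, 100, 300, 500,
          0, 5, 15, 25, 35, 50, 75, 125, 200, 250, 350, 700,
          30, 60, 90, 120, 150, 175, 200, 250, 400, 800),
    T = c(rep(100, 10), rep(100, 8), rep(40, 5), rep(70, 5),
          rep(70, 12), rep(100, 10)),
    beta = c(rep(0, 10), rep(1, 8), rep(1, 5), rep(1, 5),
             rep(0, 12), rep(1, 4), rep(0, 6)),
    label = "rich50")
}

# interior truth used in several recovery tests
interior_truth <- function() tissue_params(1.5e-3, 0.25, 150, 4)

liver_literature <- function() tissue_params(1.12e-3, 0.347, 144, 4.60)

expect_within <- function(object, expected, tol) {
  expect_true(abs(object - expected) <= tol,
              label = sprintf("|%g - %g| <= %g", object, expected, tol))
}
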