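# Element lookup tables for the organic subset handled by the package.
# period = principal quantum number of the valence shell; zv = number of
# valence electrons; masses are standard relative atomic masses.

.elements <- data.frame(
  element = c("H", "C", "N", "O", "F", "S", "Cl", "Br"),
  z       = c(1L, 6L, 7L, 8L, 9L, 16L, 17L, 35L),
  zv      = c(1L, 4L, 5L, 6L, 7L, 6L, 7L, 7L),
  period  = c(1L, 2L, 2L, 2L, 2L, 3L, 3L, 4L),
  mass    = c(1.008, 12.011, 14.007, 15.999, 18.998, 32.06, 35.45, 79.904),
  stringsAsFactors = FALSE
)

element_property <- function(element, what) {
  idx <- match(element, .elements$element)
  if (anyNA(idx)) {
    stop("unsupported element(s): ",
         paste(unique(element[is.na(idx)]), collapse = ", "))
  }
  .elements[[what]][idx]
}
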