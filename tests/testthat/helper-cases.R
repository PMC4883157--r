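# canonical toy matrices used across the suite
cm_of <- function(v) confusion_matrix(matrix(v, 2L, 2L, byrow = TRUE))

case_a <- function() cm_of(c(90, 0, 10, 0))   # always predicts dominant class
case_b <- function() cm_of(c(80, 10, 0, 10))  # errors only in dominant class
case_c <- function() cm_of(c(90, 0, 0, 10))   # perfect prediction
case_d <- function() cm_of(c(45, 45, 5, 5))   # uniformly random prediction
case_b5 <- function() cm_of(c(16, 2, 0, 2))   # case_b with 1/5 of the examples

# random valid matrix with positive row margins (cells may be zero)
random_cm <- function(max_n = 30L) {
  n1 <- sample(1:max_n, 1L); n2 <- sample(1:max_n, 1L)
  z1 <- sample(0:n1, 1L); z2 <- sample(0:n2, 1L)
  cm_of(c(z1, n1 - z1, z2, n2 - z2))
}

swap_rows <- function(cm) confusion_matrix(cm$z[2:1, ])
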