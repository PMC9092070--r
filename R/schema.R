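#' The fixed six-class label schema
#'
#' Every module shares one integer encoding of the segmentation classes:
#' Background = 0, CELL (ganglion cells) = 1, INL = 2, IPL = 3, OPL = 4,
#' RNFL = 5. The display colors are the HE-like palette used both to render
#' synthetic sections and to colorize label maps.
#'
#' @return a data.frame with columns `name`, `id`, and `r`, `g`, `b`
#'   (display color, 0-255).
#' @examples
#' label_schema()
#' @export
label_schema <- function() {
  data.frame(
    name = c("Background", "CELL", "INL", "IPL", "OPL", "RNFL"),
    id = 0:5,
    r = c(245L,  94L, 150L, 228L, 205L, 240L),
    g = c(242L,  60L, 110L, 160L, 130L, 195L),
    b = c(245L, 132L, 170L, 190L, 160L, 210L),
    stringsAsFactors = FALSE
  )
}

#' Number of segmentation classes
#' @return 6L
#' @export
n_label_classes <- function() 6L

#' Class names in id order
#' @return character vector of length 6 (index i names id i - 1)
#' @export
label_names <- function() label_schema()$name

# id lookup with validation
label_id <- function(name) {
  s <- label_schema()
  i <- match(name, s$name)
  if (any(is.na(i))) stopf("unknown label class: %s", name[is.na(i)][1])
  s$id[i]
}

# validate a label matrix against the schema
check_labels <- function(labels) {
  if (!is.matrix(labels)) stopf("labels must be a matrix")
  bad <- setdiff(unique(as.integer(labels)), 0:5)
  if (length(bad) > 0) {
    stopf("label map contains id %d, outside the 6-class schema 0..5", bad[1])
  }
  invisible(labels)
}

# HE-like palette as a 6 x 3 matrix in id order
label_palette <- function() {
  s <- label_schema()
  m <- cbind(s$r, s$g, s$b)
  rownames(m) <- s$name
  m
}
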