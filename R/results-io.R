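#' Serialize pipeline results to JSON and back
#'
#' Every analysis product in this package (distribution fits, edge lists,
#' node metrics, nested per-condition bundles) is a tibble, a classed list
#' of numeric fields, or a plain list of those. `write_results()` writes
#' such a product to JSON with an embedded class tag so that
#' `read_results()` reconstructs an object equal to the original
#' (lossless round trip, full double precision).
#'
#' @param results A pipeline product.
#' @param path JSON file path.
#' @return `write_results()` returns `path` invisibly; `read_results()`
#'   returns the reconstructed object.
#' @export
write_results <- function(results, path) {
  jsonlite::write_json(encode_result(results), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  decode_result(jsonlite::read_json(path, simplifyVector = TRUE,
                                    simplifyMatrix = FALSE))
}

result_classes <- c("power_law_fit", "piecewise_ibi_fit", "lognormal_fit",
                    "effect_size", "test_result", "slope_comparison")

encode_result <- function(x) {
  if (is.data.frame(x)) {
    return(list(`.type` = "tbl", data = as.data.frame(x),
                n = nrow(x)))
  }
  if (is.list(x)) {
    cls <- intersect(class(x), result_classes)
    enc <- purrr::map(unclass(x), encode_result)
    if (length(cls)) enc$`.type` <- cls[1]
    return(enc)
  }
  x
}

decode_result <- function(x) {
  if (!is.list(x)) return(x)
  type <- x$`.type`
  x$`.type` <- NULL
  if (identical(type, "tbl")) {
    d <- x$data
    # a zero-row or one-column frame simplifies awkwardly; rebuild
    if (is.null(d) || (is.list(d) && !is.data.frame(d) && !length(d))) {
      return(tibble::tibble())
    }
    return(tibble::as_tibble(as.data.frame(d, stringsAsFactors = FALSE)))
  }
  out <- purrr::map(x, decode_result)
  if (!is.null(type)) {
    class(out) <- type
  }
  out
}
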