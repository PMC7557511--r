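#' Facial action classes
#'
#' The decoder distinguishes four voluntary facial actions. Two are bilateral
#' brow movements (raising and furrowing the brow) and two are unilateral
#' mouth movements (left and right smirk). Their class labels are used
#' throughout the package: in event tables, epoch labels, the classifier
#' target encoding and the prosthesis command mapping.
#'
#' @return Character vector of the four canonical action labels, in codec
#'   order (see [encode_actions()]).
#' @export
#' @examples
#' action_classes()
action_classes <- function() {
  c("furrowing_brow", "raising_brow", "left_smirking", "right_smirking")
}

assert_action <- function(action) {
  if (!is.character(action) || length(action) != 1L ||
      !(action %in% action_classes())) {
    stop("unknown facial action '", paste(action, collapse = ","),
         "'; expected one of: ", paste(action_classes(), collapse = ", "),
         call. = FALSE)
  }
  action
}

#' Two-bit label codec for the four facial actions
#'
#' The classifier has two log-sigmoid output units; each action is encoded as
#' a pair of bits: furrowing brow = (0,0), raising brow = (0,1), left smirk =
#' (1,0), right smirk = (1,1). `encode_actions` maps labels to an n x 2 target
#' matrix; `decode_outputs` thresholds continuous network outputs at 0.5 and
#' maps the bit pair back to a label. The mapping is a bijection over the four
#' classes.
#'
#' @param actions Character vector of action labels.
#' @return `encode_actions`: numeric matrix with one row per action and two
#'   columns (`y1`, `y2`).
#' @export
#' @examples
#' encode_actions(c("furrowing_brow", "right_smirking"))
#' decode_outputs(matrix(c(0.9, 0.1), nrow = 1))  # bits (1,0) -> left smirk
encode_actions <- function(actions) {
  codes <- rbind(
    furrowing_brow = c(0, 0),
    raising_brow   = c(0, 1),
    left_smirking  = c(1, 0),
    right_smirking = c(1, 1)
  )
  bad <- setdiff(unique(actions), rownames(codes))
  if (length(bad) > 0) {
    stop("unknown facial action(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out <- codes[actions, , drop = FALSE]
  dimnames(out) <- list(NULL, c("y1", "y2"))
  out
}

#' @rdname encode_actions
#' @param outputs Numeric matrix (n x 2) of network outputs in (0,1), or a
#'   length-2 vector for a single sample.
#' @return `decode_outputs`: character vector of decoded action labels.
#' @export
decode_outputs <- function(outputs) {
  if (is.null(dim(outputs))) outputs <- matrix(outputs, nrow = 1)
  stopifnot(ncol(outputs) == 2)
  bits <- outputs >= 0.5
  idx <- 1L + bits[, 2L] + 2L * bits[, 1L]  # (y1,y2) -> 00,01,10,11
  action_classes()[idx]
}
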