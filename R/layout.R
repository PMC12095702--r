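#' Electrode layout with cortical geometry and routing adjacency
#'
#' Describes where each channel's electrode sits on the cortex (grid row and
#' column, position in micrometers) and how the channels are routed through
#' the recording chain. The two are distinct: volume conduction acts on
#' cortical distance, crosstalk acts on routing adjacency. In the modeled
#' system the channels of each grid column are wired adjacently throughout
#' substrate, connector and headstage, so the routing groups are the grid
#' columns and the within-group order runs from the top row (A) down (D).
#'
#' Channels are numbered row-major: channel 1 is the top-left electrode.
#'
#' @param n_rows,n_cols grid dimensions (default 4 x 4)
#' @param pitch_um electrode pitch in micrometers (default 750)
#' @return An object of class `electrode_layout`: a data frame with columns
#'   `channel`, `row`, `col` (0-based), `x_um`, `y_um`, `routing_group`,
#'   `routing_order`.
#' @examples
#' lay <- electrode_layout()
#' subset(lay, routing_group == 1)$channel   # 1, 5, 9, 13
#' @export
electrode_layout <- function(n_rows = 4, n_cols = 4, pitch_um = 750) {
  stopifnot(n_rows >= 1, n_cols >= 1, pitch_um > 0)
  row <- rep(0:(n_rows - 1), each = n_cols)
  col <- rep(0:(n_cols - 1), times = n_rows)
  d <- data.frame(
    channel = seq_len(n_rows * n_cols),
    row = row, col = col,
    x_um = col * pitch_um,
    y_um = row * pitch_um,
    routing_group = col + 1L,   # grid columns are routed together
    routing_order = row + 1L)   # top electrode of each column is line A
  class(d) <- c("electrode_layout", "data.frame")
  d
}

validate_layout <- function(layout, group_size = NULL) {
  need <- c("channel", "x_um", "y_um", "routing_group", "routing_order")
  if (!all(need %in% names(layout)))
    stop("layout must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(layout$channel))
    stop("duplicate channels in layout", call. = FALSE)
  if (!is.null(group_size)) {
    sz <- table(layout$routing_group)
    if (any(sz != group_size))
      stop("every routing group must have exactly ", group_size,
           " channels (got ", paste(sz, collapse = ","), ")", call. = FALSE)
  }
  invisible(layout)
}

# Euclidean cortical distance (um) between two channels
layout_distance <- function(layout, a, b) {
  ia <- match(a, layout$channel); ib <- match(b, layout$channel)
  sqrt((layout$x_um[ia] - layout$x_um[ib])^2 +
       (layout$y_um[ia] - layout$y_um[ib])^2)
}

# routing groups as an ordered list of channel vectors (order A..D)
routing_groups <- function(layout) {
  lapply(split(layout, layout$routing_group), function(g) {
    g$channel[order(g$routing_order)]
  })
}

#' Read and write an electrode layout as JSON
#'
#' @param path JSON file path
#' @return `read_layout_json()` returns an `electrode_layout`;
#'   `write_layout_json()` returns `path` invisibly.
#' @export
read_layout_json <- function(path) {
  d <- jsonlite::fromJSON(path)
  d <- as.data.frame(d)
  validate_layout(d)
  class(d) <- c("electrode_layout", "data.frame")
  d
}

#' @rdname read_layout_json
#' @param layout an `electrode_layout`
#' @export
write_layout_json <- function(layout, path) {
  validate_layout(layout)
  jsonlite::write_json(as.data.frame(unclass(layout)), path,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
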