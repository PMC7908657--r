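#' Backbone configuration
#'
#' Configures the full-scale connected deep-layer-aggregation feature
#' extractor. The backbone has \code{I} hierarchy levels; level \code{i}
#' operates at spatial scale \code{4 * 2^i} relative to the input (a two-block
#' stride-2 stem takes scale 1 to scale 4 first). Level \code{i} contains
#' \code{J - (2 i + 1)} aggregation nodes; each node applies a 3x3
#' convolution + ReLU to the concatenation of its inputs. A node at dense
#' position \code{j = 0} receives one input from the level below (stride-2
#' convolution); later nodes receive an upsampled (x2 bilinear + 1x1
#' projection) output of the coarser level plus every earlier same-level
#' output (the dense skip connections). The last node of each of the three
#' finest levels is exposed as Out 4 / Out 8 / Out 16.
#'
#' \code{J} must equal \code{2 * I}: the wiring is only well formed when the
#' per-level node counts shrink by two per level down to a single node at the
#' coarsest level, which the bound \code{J - (2 i + 1)} delivers exactly at
#' \code{J = 2 I}.
#'
#' @param I number of downsampling levels (>= 2; 4 gives scales 4..32).
#' @param J number of dense positions governing per-level node counts
#'   (must equal \code{2 * I}).
#' @param channels_per_level integer vector of length \code{I}; feature
#'   channels emitted by every node of each level. Defaults to the compact
#'   test profile \code{c(16, 32, 64, 128)}; the reference training profile
#'   uses \code{c(64, 128, 256, 512)}.
#' @param in_channels input channels (3 for the 2.5D three-slice stack).
#' @param use_deformable placeholder flag for deformable dense convolutions;
#'   the CPU implementation substitutes standard convolutions and keeps the
#'   flag for config compatibility.
#' @return a \code{backbone_config} list.
#' @export
backbone_config <- function(I = 4L, J = 2L * I,
                            channels_per_level = c(16L, 32L, 64L, 128L)[seq_len(I)],
                            in_channels = 3L, use_deformable = FALSE) {
  I <- as.integer(I); J <- as.integer(J)
  if (I < 2) stop("backbone needs I >= 2 levels")
  if (J != 2L * I)
    stop("structural error: J must equal 2*I (got J=", J, ", I=", I,
         "); otherwise the coarsest level's dense positions have no coarser ",
         "level to upsample from")
  if (length(channels_per_level) != I)
    stop("channels_per_level must have one entry per level")
  structure(list(I = I, J = J,
                 channels_per_level = as.integer(channels_per_level),
                 in_channels = as.integer(in_channels),
                 use_deformable = isTRUE(use_deformable)),
            class = "backbone_config")
}

# nodes per level: positions j = 0 .. level_positions(i) - 1
level_positions <- function(config, i) config$J - (2L * i + 1L)

#' Predecessors of a backbone aggregation node
#'
#' Pure function giving the labeled inputs of node (i, j):
#' \itemize{
#'   \item \code{j = 0}: a single \code{dense_conv_input} from the level
#'     below (the stem for level 0), entering through a stride-2 convolution.
#'   \item middle positions: one \code{upsample_input} from node
#'     \code{(i+1, j-1)} plus \code{same_level_skip} edges from all
#'     \code{(i, 0..j-1)}.
#'   \item the last position of a level: the upsample input skips one node
#'     and comes from \code{(i+1, j-2)} — the last node of the coarser level
#'     — plus all same-level predecessors.
#' }
#'
#' @param i level index (0-based).
#' @param j dense position within the level (0-based).
#' @param config a \code{\link{backbone_config}}.
#' @return a list of edges, each \code{list(role, from)} where \code{from} is
#'   \code{"stem"} or an integer vector \code{c(i, j)}.
#' @export
node_inputs <- function(i, j, config) {
  P <- level_positions(config, i)
  if (i < 0 || i >= config$I || j < 0 || j >= P)
    stop("structural error: no node (", i, ", ", j, ") in this backbone")
  if (j == 0) {
    from <- if (i == 0) "stem" else c(i - 1L, 0L)
    return(list(list(role = "dense_conv_input", from = from)))
  }
  up_j <- if (j < P - 1L) j - 1L else j - 2L
  edges <- list(list(role = "upsample_input", from = c(i + 1L, up_j)))
  for (k in seq_len(j) - 1L)
    edges <- c(edges, list(list(role = "same_level_skip", from = c(i, k))))
  edges
}

#' Build the backbone aggregation graph
#'
#' Enumerates every node, wires it according to \code{\link{node_inputs}},
#' and computes a topological evaluation order. The output frontier is the
#' last node of each level at scales 4, 8 and 16 (levels 0..2); coarser
#' levels are internal.
#'
#' @param config a \code{\link{backbone_config}}.
#' @return a \code{backbone_graph} list with \code{nodes} (data frame i, j,
#'   scale, last), \code{edges}, \code{order} (list of c(i, j) in evaluation
#'   order) and \code{output_scales}.
#' @export
build_graph <- function(config) {
  nodes <- do.call(rbind, lapply(seq_len(config$I) - 1L, function(i) {
    P <- level_positions(config, i)
    data.frame(i = i, j = seq_len(P) - 1L, scale = 4L * 2L^i,
               last = seq_len(P) - 1L == P - 1L)
  }))
  edges <- list()
  for (r in seq_len(nrow(nodes))) {
    ins <- node_inputs(nodes$i[r], nodes$j[r], config)
    for (e in ins) {
      if (!identical(e$from, "stem")) {
        fi <- e$from[1]; fj <- e$from[2]
        if (fi >= config$I || fj < 0 || fj >= level_positions(config, fi))
          stop("structural error: node (", nodes$i[r], ", ", nodes$j[r],
               ") references nonexistent input (", fi, ", ", fj, ")")
      }
      edges[[length(edges) + 1]] <- c(e, list(to = c(nodes$i[r], nodes$j[r])))
    }
  }
  ord <- nodes[order(nodes$j, nodes$i), c("i", "j")]
  out_levels <- which(4L * 2L^(seq_len(config$I) - 1L) <= 16L) - 1L
  out_levels <- out_levels[out_levels < config$I]
  structure(list(config = config, nodes = nodes, edges = edges,
                 order = lapply(seq_len(nrow(ord)),
                                function(r) c(ord$i[r], ord$j[r])),
                 output_scales = 4L * 2L^out_levels),
            class = "backbone_graph")
}

node_key <- function(i, j) paste0("n", i, "_", j)

# create all backbone parameters in a store under the given prefix
backbone_init <- function(store, config, prefix = "bb") {
  ch <- config$channels_per_level
  param_add(store, paste0(prefix, ".stem1.w"),
            init_conv_w(3, 3, config$in_channels, ch[1]))
  param_add(store, paste0(prefix, ".stem1.b"), numeric(ch[1]))
  param_add(store, paste0(prefix, ".stem2.w"), init_conv_w(3, 3, ch[1], ch[1]))
  param_add(store, paste0(prefix, ".stem2.b"), numeric(ch[1]))
  for (i in seq_len(config$I) - 1L) {
    ci <- ch[i + 1]
    for (j in seq_len(level_positions(config, i)) - 1L) {
      key <- paste0(prefix, ".", node_key(i, j))
      cin <- if (j == 0) {
        if (i == 0) ch[1] else ch[i]
      } else (j + 1L) * ci  # j same-level inputs + 1 projected upsample
      param_add(store, paste0(key, ".w"), init_conv_w(3, 3, cin, ci))
      param_add(store, paste0(key, ".b"), numeric(ci))
      if (j > 0) {
        param_add(store, paste0(key, ".up.w"), init_conv_w(1, 1, ch[i + 2], ci))
        param_add(store, paste0(key, ".up.b"), numeric(ci))
      }
    }
  }
  invisible(store)
}

# run the backbone on one 2.5D stack node; returns list(outputs = named list
# of tape nodes keyed by scale, nodes = all node outputs)
backbone_forward <- function(tp, x, graph, prefix = "bb") {
  config <- graph$config
  d <- dim(x$v)
  div <- 4L * 2L^(config$I - 1L)
  if (d[1] %% div != 0 || d[2] %% div != 0)
    stop("input height/width must be divisible by ", div,
         " (got ", d[1], "x", d[2], "); pad the input first")
  if (d[3] != config$in_channels)
    stop("input has ", d[3], " channels; backbone expects ", config$in_channels)
  s1 <- op_relu(tp, op_conv(tp, x, paste0(prefix, ".stem1.w"),
                            paste0(prefix, ".stem1.b"), stride = 2L))
  stem <- op_relu(tp, op_conv(tp, s1, paste0(prefix, ".stem2.w"),
                              paste0(prefix, ".stem2.b"), stride = 2L))
  outs <- list(stem = stem)
  for (ij in graph$order) {
    i <- ij[1]; j <- ij[2]
    key <- paste0(prefix, ".", node_key(i, j))
    ins <- node_inputs(i, j, config)
    if (j == 0) {
      src <- if (identical(ins[[1]]$from, "stem")) outs$stem
             else outs[[node_key(ins[[1]]$from[1], ins[[1]]$from[2])]]
      stride <- if (identical(ins[[1]]$from, "stem")) 1L else 2L
      h <- op_relu(tp, op_conv(tp, src, paste0(key, ".w"), paste0(key, ".b"),
                               stride = stride))
    } else {
      gathered <- lapply(ins, function(e) {
        src <- outs[[node_key(e$from[1], e$from[2])]]
        if (e$role == "upsample_input") {
          up <- op_upsample2x(tp, src)
          op_conv(tp, up, paste0(key, ".up.w"), paste0(key, ".up.b"))
        } else src
      })
      h <- op_relu(tp, op_conv(tp, op_concat(tp, gathered),
                               paste0(key, ".w"), paste0(key, ".b")))
    }
    outs[[node_key(i, j)]] <- h
  }
  outputs <- list()
  for (sc in graph$output_scales) {
    i <- as.integer(log2(sc / 4))
    outputs[[as.character(sc)]] <-
      outs[[node_key(i, level_positions(config, i) - 1L)]]
  }
  list(outputs = outputs, nodes = outs)
}

#' Export the backbone wiring as DOT text
#'
#' @param graph a \code{backbone_graph}.
#' @param path optional file to write to.
#' @return the DOT source as a character scalar (invisibly if written).
#' @export
graph_to_dot <- function(graph, path = NULL) {
  lines <- c("digraph backbone {", "  rankdir=BT;",
             "  stem [shape=box];")
  for (r in seq_len(nrow(graph$nodes))) {
    n <- graph$nodes[r, ]
    lines <- c(lines, sprintf(
      "  %s [label=\"(%d,%d) /%d%s\"];", node_key(n$i, n$j), n$i, n$j,
      n$scale, if (n$last && n$scale %in% graph$output_scales) " out" else ""))
  }
  for (e in graph$edges) {
    from <- if (identical(e$from, "stem")) "stem" else node_key(e$from[1], e$from[2])
    lines <- c(lines, sprintf("  %s -> %s [label=\"%s\"];",
                              from, node_key(e$to[1], e$to[2]), e$role))
  }
  dot <- paste(c(lines, "}"), collapse = "\n")
  if (!is.null(path)) {
    writeLines(dot, path)
    return(invisible(dot))
  }
  dot
}
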