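# Independent brute-force oracles used to cross-check the production code.

# Literal transcription of greedy NMS: select the highest-confidence box
# (ties: smaller y, then x, then index), move it to the kept set, drop every
# remaining box with IOU strictly greater than lambda, repeat until empty.
# Deliberately quadratic and list-based; shares no code with nms().
brute_force_nms <- function(boxes, lambda) {
  P <- seq_len(nrow(boxes))
  D <- integer(0)
  iou_pair <- function(i, j) {
    ax <- boxes$x[i]; ay <- boxes$y[i]; aw <- boxes$width[i]; ah <- boxes$height[i]
    bx <- boxes$x[j]; by <- boxes$y[j]; bw <- boxes$width[j]; bh <- boxes$height[j]
    ix <- max(0, min(ax + aw, bx + bw) - max(ax, bx))
    iy <- max(0, min(ay + ah, by + bh) - max(ay, by))
    inter <- ix * iy
    inter / (aw * ah + bw * bh - inter)
  }
  while (length(P) > 0) {
    best <- P[1]
    for (i in P) {
      if (boxes$confidence[i] > boxes$confidence[best] ||
          (boxes$confidence[i] == boxes$confidence[best] &&
           (boxes$y[i] < boxes$y[best] ||
            (boxes$y[i] == boxes$y[best] && boxes$x[i] < boxes$x[best]) ||
            (boxes$y[i] == boxes$y[best] && boxes$x[i] == boxes$x[best] &&
             i < best)))) {
        best <- i
      }
    }
    D <- c(D, best)
    P <- setdiff(P, best)
    drop <- P[vapply(P, function(j) iou_pair(best, j) > lambda, logical(1))]
    P <- setdiff(P, drop)
  }
  boxes[D, , drop = FALSE]
}

random_scored_boxes <- function(n, seed, max_xy = 100, max_wh = 30) {
  maizecount:::with_seed(seed, {
    data.frame(x = runif(n, 0, max_xy), y = runif(n, 0, max_xy),
               width = runif(n, 1, max_wh), height = runif(n, 1, max_wh),
               confidence = runif(n))
  })
}
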