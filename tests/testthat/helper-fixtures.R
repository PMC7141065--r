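# small in-code fixtures shared across tests

# a 2x2 AOI layout on a 100x100 stimulus, labels A-D in reading order
tiny_layout <- function() {
  aoiset("stim1", 100, 100, data.frame(
    label = c("A", "B", "C", "D"),
    x0 = c(0, 50, 0, 50), y0 = c(0, 0, 50, 50),
    x1 = c(50, 100, 50, 100), y1 = c(50, 50, 100, 100)))
}

# fixation table visiting the given AOI labels at their centres, 100 ms each
fixations_at <- function(labels, aoiset, participant = "P1") {
  a <- aoiset$aois
  i <- match(labels, a$label)
  data.frame(participant = participant, stimulus = aoiset$stimulus,
             onset_ms = seq_along(labels) * 200,
             x = (a$x0[i] + a$x1[i]) / 2, y = (a$y0[i] + a$y1[i]) / 2,
             duration_ms = 100, stringsAsFactors = FALSE)
}

write_tsv_fixture <- function(df, path = withr::local_tempfile(fileext = ".tsv",
                                                               .local_envir = parent.frame())) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
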