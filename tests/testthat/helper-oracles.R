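## Independent brute-force oracles used to check the package's classifiers
## and scores. Deliberately share no code with the implementation: plain
## string scanning with while loops, and direct segment-list scans.

.oc_comp <- c(A = "T", C = "G", G = "C", T = "A")

.oc_revcomp <- function(x) {
    out <- ""
    for (i in nchar(x):1)
        out <- paste0(out, .oc_comp[[substr(x, i, i)]])
    out
}

## SBS96 channel by direct string scanning
oracleSbs <- function(chrom, pos, ref, alt, genomeChar) {
    s <- genomeChar[[chrom]]
    stopifnot(substr(s, pos, pos) == ref)
    up <- substr(s, pos - 1, pos - 1)
    dn <- substr(s, pos + 1, pos + 1)
    if (ref == "A" || ref == "G") {
        tmp <- up
        up <- .oc_comp[[dn]]
        dn <- .oc_comp[[tmp]]
        ref <- .oc_comp[[ref]]
        alt <- .oc_comp[[alt]]
    }
    paste0(up, "[", ref, ">", alt, "]", dn)
}

## ID83 channel by brute-force scanning
oracleIndel <- function(chrom, pos, ref, alt, genomeChar) {
    s <- genomeChar[[chrom]]
    n <- nchar(s)
    if (alt == "-") {
        L <- nchar(ref)
        ## shift left while the base before equals the base at the del end
        while (pos > 1 &&
               substr(s, pos - 1, pos - 1) == substr(s, pos + L - 1,
                                                     pos + L - 1))
            pos <- pos - 1
        del <- substr(s, pos, pos + L - 1)
        ## walk 3' counting extra tandem copies
        cnt <- 0
        q <- pos + L
        while (q + L - 1 <= n && substr(s, q, q + L - 1) == del) {
            cnt <- cnt + 1
            q <- q + L
        }
        if (L == 1) {
            b <- del
            if (b == "A" || b == "G") b <- .oc_comp[[b]]
            return(paste0("1:Del:", b, ":", min(cnt, 5)))
        }
        if (cnt >= 1)
            return(paste0(min(L, 5), ":Del:R:", min(cnt, 5)))
        m3 <- 0
        while (m3 < L - 1 && pos + L + m3 <= n &&
               substr(s, pos + L + m3, pos + L + m3) ==
               substr(del, m3 + 1, m3 + 1))
            m3 <- m3 + 1
        m5 <- 0
        while (m5 < L - 1 && pos - 1 - m5 >= 1 &&
               substr(s, pos - 1 - m5, pos - 1 - m5) ==
               substr(del, L - m5, L - m5))
            m5 <- m5 + 1
        m <- min(max(m3, m5), L - 1, 5)
        if (m == 0) return(paste0(min(L, 5), ":Del:R:0"))
        paste0(min(L, 5), ":Del:M:", m)
    } else {
        ins <- alt
        L <- nchar(ins)
        while (pos >= 1 && substr(s, pos, pos) == substr(ins, L, L)) {
            ins <- paste0(substr(ins, L, L), substr(ins, 1, L - 1))
            pos <- pos - 1
        }
        cnt <- 0
        q <- pos + 1
        while (q + L - 1 <= n && substr(s, q, q + L - 1) == ins) {
            cnt <- cnt + 1
            q <- q + L
        }
        if (L == 1) {
            b <- ins
            if (b == "A" || b == "G") b <- .oc_comp[[b]]
            return(paste0("1:Ins:", b, ":", min(cnt, 5)))
        }
        paste0(min(L, 5), ":Ins:R:", min(cnt, 5))
    }
}

## ---- scar-score oracles: direct scans over segment lists ---------------

.oc_layout <- function(layout, chrom) {
    i <- which(layout@chrom == chrom)
    c(len = layout@length[i], cs = layout@centromereStart[i],
      ce = layout@centromereEnd[i])
}

oracleLoh <- function(segments, layout, minBp = 15e6) {
    total <- 0
    for (chrom in unique(segments$chrom)) {
        g <- .oc_layout(layout, chrom)
        s <- segments[segments$chrom == chrom, ]
        s <- s[order(s$start), ]
        isLoh <- s$minor_cn == 0 & s$major_cn >= 1
        i <- 1
        while (i <= nrow(s)) {
            if (!isLoh[i]) { i <- i + 1; next }
            j <- i
            while (j < nrow(s) && isLoh[j + 1]) j <- j + 1
            bp <- sum(s$end[i:j] - s$start[i:j] + 1)
            spansAll <- s$start[i] <= 1 && s$end[j] >= g[["len"]]
            if (bp > minBp && !spansAll) total <- total + 1
            i <- j + 1
        }
    }
    total
}

oracleNtai <- function(segments, layout, margin = 0) {
    total <- 0
    for (r in seq_len(nrow(segments))) {
        g <- .oc_layout(layout, segments$chrom[r])
        if (segments$major_cn[r] == segments$minor_cn[r]) next
        atEnd <- segments$start[r] <= 1 + margin ||
            segments$end[r] >= g[["len"]] - margin
        throughCen <- segments$start[r] < g[["cs"]] &&
            segments$end[r] > g[["ce"]]
        if (atEnd && !throughCen) total <- total + 1
    }
    total
}

oracleLst <- function(segments, layout, minBp = 10e6) {
    total <- 0
    for (chrom in unique(segments$chrom)) {
        g <- .oc_layout(layout, chrom)
        s <- segments[segments$chrom == chrom, ]
        s <- s[order(s$start), ]
        for (arm in c("p", "q")) {
            lo <- if (arm == "p") 1 else g[["ce"]] + 1
            hi <- if (arm == "p") g[["cs"]] - 1 else g[["len"]]
            a <- s[s$end >= lo & s$start <= hi, ]
            if (nrow(a) < 2) next
            a$start[a$start < lo] <- lo
            a$end[a$end > hi] <- hi
            for (i in 1:(nrow(a) - 1)) {
                differs <- a$major_cn[i] != a$major_cn[i + 1] ||
                    a$minor_cn[i] != a$minor_cn[i + 1]
                long1 <- (a$end[i] - a$start[i] + 1) >= minBp
                long2 <- (a$end[i + 1] - a$start[i + 1] + 1) >= minBp
                if (differs && long1 && long2) total <- total + 1
            }
        }
    }
    total
}
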