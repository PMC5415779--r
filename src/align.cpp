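#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>

using namespace Rcpp;

// Seed-and-extend ungapped alignment against a small multi-record reference.
// 2-bit encoded k-mer seed index (k <= 15), exhaustive candidate evaluation,
// deterministic leftmost tie-break.  Intended for desk-scale synthetic
// genomes; real data enters the pipeline as SAM/BAM from an external aligner.

static inline int baseCode(char c) {
    switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
    }
}

static inline char complBase(char c) {
    switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
    }
}

struct Candidate {
    int ref;
    int pos;      // 0-based leftmost
    bool fwd;
    int mism;
};

// [[Rcpp::export(name = ".cppAlign")]]
DataFrame cppAlign(CharacterVector readSeqs, CharacterVector refSeqs,
                   int k, int maxMismatch) {
    const int nref = refSeqs.size();
    std::vector<std::string> refs(nref);
    for (int i = 0; i < nref; ++i) refs[i] = as<std::string>(refSeqs[i]);

    if (k < 4 || k > 15) stop("seed length k must be in [4, 15]");

    // seed index: kmer code -> packed (ref << 32 | pos)
    std::unordered_map<uint32_t, std::vector<uint64_t> > index;
    const uint32_t mask = (1u << (2 * k)) - 1u;
    for (int r = 0; r < nref; ++r) {
        const std::string &s = refs[r];
        if ((int)s.size() < k) continue;
        uint32_t code = 0;
        int valid = 0;
        for (size_t i = 0; i < s.size(); ++i) {
            int b = baseCode(s[i]);
            if (b < 0) { valid = 0; code = 0; continue; }
            code = ((code << 2) | (uint32_t)b) & mask;
            if (++valid >= k)
                index[code].push_back(((uint64_t)r << 32) |
                                      (uint64_t)(i - k + 1));
        }
    }

    const int nreads = readSeqs.size();
    IntegerVector outRef(nreads), outPos(nreads), outMism(nreads),
        outBest(nreads);
    LogicalVector outFwd(nreads), outMapped(nreads);

    for (int q = 0; q < nreads; ++q) {
        std::string rd = as<std::string>(readSeqs[q]);
        const int len = (int)rd.size();
        if (len < k) stop("read shorter than seed length k");
        std::string rc(len, 'N');
        for (int i = 0; i < len; ++i) rc[i] = complBase(rd[len - 1 - i]);

        // collect candidate (ref, pos, strand) triples, deduplicated
        std::vector<Candidate> cands;
        for (int strand = 0; strand < 2; ++strand) {
            const std::string &seq = strand == 0 ? rd : rc;
            std::vector<int> offs;
            for (int o = 0; o + k <= len; o += k) offs.push_back(o);
            if (offs.empty() || offs.back() != len - k)
                offs.push_back(len - k);
            for (size_t oi = 0; oi < offs.size(); ++oi) {
                int o = offs[oi];
                uint32_t code = 0;
                bool ok = true;
                for (int j = 0; j < k; ++j) {
                    int b = baseCode(seq[o + j]);
                    if (b < 0) { ok = false; break; }
                    code = (code << 2) | (uint32_t)b;
                }
                if (!ok) continue;
                std::unordered_map<uint32_t,
                    std::vector<uint64_t> >::const_iterator hit =
                    index.find(code);
                if (hit == index.end()) continue;
                for (size_t h = 0; h < hit->second.size(); ++h) {
                    int r = (int)(hit->second[h] >> 32);
                    int p = (int)(hit->second[h] & 0xffffffffu) - o;
                    if (p < 0 || p + len > (int)refs[r].size()) continue;
                    bool dup = false;
                    for (size_t c = 0; c < cands.size(); ++c)
                        if (cands[c].ref == r && cands[c].pos == p &&
                            cands[c].fwd == (strand == 0)) { dup = true; break; }
                    if (!dup) {
                        Candidate cd;
                        cd.ref = r; cd.pos = p; cd.fwd = (strand == 0);
                        cd.mism = 0;
                        cands.push_back(cd);
                    }
                }
            }
        }

        // ungapped extension: count mismatches over the full read
        int best = maxMismatch + 1, nbest = 0, bi = -1;
        for (size_t c = 0; c < cands.size(); ++c) {
            const std::string &seq = cands[c].fwd ? rd : rc;
            const std::string &ref = refs[cands[c].ref];
            int m = 0;
            for (int j = 0; j < len && m <= maxMismatch; ++j)
                if (seq[j] != ref[cands[c].pos + j]) ++m;
            cands[c].mism = m;
            if (m > maxMismatch) continue;
            if (m < best) { best = m; nbest = 1; bi = (int)c; }
            else if (m == best) {
                ++nbest;
                // leftmost tie-break: record order, then coordinate, then fwd
                const Candidate &b = cands[bi];
                if (cands[c].ref < b.ref ||
                    (cands[c].ref == b.ref && cands[c].pos < b.pos) ||
                    (cands[c].ref == b.ref && cands[c].pos == b.pos &&
                     cands[c].fwd && !b.fwd))
                    bi = (int)c;
            }
        }

        if (bi < 0) {
            outMapped[q] = false;
            outRef[q] = NA_INTEGER; outPos[q] = NA_INTEGER;
            outMism[q] = NA_INTEGER; outBest[q] = 0; outFwd[q] = NA_LOGICAL;
        } else {
            outMapped[q] = true;
            outRef[q] = cands[bi].ref + 1;        // 1-based record index
            outPos[q] = cands[bi].pos + 1;        // 1-based leftmost
            outMism[q] = cands[bi].mism;
            outBest[q] = nbest;
            outFwd[q] = cands[bi].fwd;
        }
    }

    return DataFrame::create(
        Named("refIndex") = outRef, Named("pos") = outPos,
        Named("forward") = outFwd, Named("mismatches") = outMism,
        Named("nBest") = outBest, Named("mapped") = outMapped);
}
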