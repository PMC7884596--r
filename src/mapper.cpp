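#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// 2-bit nucleotide encoding; anything non-ACGT -> 4
static inline int base2int(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4;
    }
}

static inline char comp(char c) {
    switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
    default: return 'N';
    }
}

static std::string revcomp(const std::string& s) {
    std::string r(s.rbegin(), s.rend());
    for (size_t i = 0; i < r.size(); ++i) r[i] = comp(r[i]);
    return r;
}

typedef std::unordered_map<uint32_t, std::vector<int> > KmerIndex;

static KmerIndex build_index(const std::string& seq, int k) {
    KmerIndex idx;
    int n = (int) seq.size();
    if (n < k) return idx;
    uint32_t kmer = 0, mask = (k >= 16) ? 0xFFFFFFFFu : ((1u << (2 * k)) - 1);
    int valid = 0;
    for (int i = 0; i < n; ++i) {
        int b = base2int(seq[i]);
        if (b > 3) { valid = 0; kmer = 0; continue; }
        kmer = ((kmer << 2) | (uint32_t) b) & mask;
        if (++valid >= k) idx[kmer].push_back(i - k + 1);
    }
    return idx;
}

// mismatches between read placed at 0-based contig offset `off` over the
// overlap region only; returns (overlap_len, mismatches)
static inline void overlap_mm(const std::string& read, const std::string& contig,
                              int off, int& overlap, int& mm) {
    int rl = (int) read.size(), cl = (int) contig.size();
    int rs = std::max(0, -off);
    int re = std::min(rl, cl - off);
    overlap = re - rs;
    mm = 0;
    if (overlap <= 0) { overlap = 0; return; }
    for (int i = rs; i < re; ++i) {
        char a = read[i], b = contig[off + i];
        int ai = base2int(a), bi = base2int(b);
        if (ai > 3 || bi > 3 || ai != bi) ++mm;  // ambiguous bases count as mismatches
    }
}

struct Hit {
    int contig; int strand; int off; int overlap; int mm;
};

// Candidate diagonals for one oriented read against one contig index.
static void candidate_diags(const std::string& read, const KmerIndex& idx, int k,
                            std::vector<int>& diags) {
    std::unordered_map<int, int> votes;
    int rl = (int) read.size();
    if (rl < k) return;
    uint32_t kmer = 0, mask = (k >= 16) ? 0xFFFFFFFFu : ((1u << (2 * k)) - 1);
    int valid = 0;
    for (int i = 0; i < rl; ++i) {
        int b = base2int(read[i]);
        if (b > 3) { valid = 0; kmer = 0; continue; }
        kmer = ((kmer << 2) | (uint32_t) b) & mask;
        if (++valid >= k) {
            KmerIndex::const_iterator it = idx.find(kmer);
            if (it != idx.end()) {
                int rpos = i - k + 1;
                for (size_t j = 0; j < it->second.size(); ++j)
                    votes[it->second[j] - rpos]++;
            }
        }
    }
    if (votes.empty()) return;
    int maxv = 0;
    for (std::unordered_map<int, int>::iterator it = votes.begin(); it != votes.end(); ++it)
        if (it->second > maxv) maxv = it->second;
    // short queries (reads): the true diagonal dominates the votes, a tight
    // cap suffices. Long queries (contig-vs-contig overlap detection): a
    // short true end overlap can be outvoted by repeat diagonals, so search
    // wide.
    bool longq = rl > 1000;
    int thr = std::max(1, maxv / (longq ? 16 : 4));
    std::vector<std::pair<int, int> > cand;  // (-votes, diag), best-first
    for (std::unordered_map<int, int>::iterator it = votes.begin(); it != votes.end(); ++it)
        if (it->second >= thr) cand.push_back(std::make_pair(-it->second, it->first));
    std::sort(cand.begin(), cand.end());
    size_t keep = std::min(cand.size(), (size_t) (longq ? 128 : 16));
    for (size_t i = 0; i < keep; ++i) diags.push_back(cand[i].second);
    std::sort(diags.begin(), diags.end());
}

// Best ungapped placement of each read on each contig (both strands).
// Candidate diagonals meeting the acceptance gate (overlap >= min_overlap
// and identity >= min_identity) are preferred over non-qualifying ones (so
// a short clean end overlap beats a long dirty repeat diagonal); within a
// tier the diagonal with the most matches wins. Returns one row per
// (read, contig) pair that had any k-mer seed: read (1-based), contig
// (1-based), strand (+1/-1), offset (0-based, may be negative = left
// overhang), overlap, mismatches, qualified.
// [[Rcpp::export]]
DataFrame cpp_best_hits(CharacterVector reads, CharacterVector contigs, int k,
                        int min_overlap, double min_identity) {
    int nc = contigs.size(), nr = reads.size();
    std::vector<std::string> cseq(nc);
    std::vector<KmerIndex> idx(nc);
    for (int j = 0; j < nc; ++j) {
        cseq[j] = as<std::string>(contigs[j]);
        idx[j] = build_index(cseq[j], k);
    }
    std::vector<int> o_read, o_contig, o_strand, o_off, o_ov, o_mm, o_q;
    for (int i = 0; i < nr; ++i) {
        std::string fwd = as<std::string>(reads[i]);
        std::string rev = revcomp(fwd);
        for (int j = 0; j < nc; ++j) {
            bool have = false, bestq = false; Hit best; best.mm = 0; best.overlap = 0;
            for (int s = 0; s < 2; ++s) {
                const std::string& r = (s == 0) ? fwd : rev;
                std::vector<int> diags;
                candidate_diags(r, idx[j], k, diags);
                for (size_t d = 0; d < diags.size(); ++d) {
                    int overlap, mm;
                    overlap_mm(r, cseq[j], diags[d], overlap, mm);
                    if (overlap <= 0) continue;
                    bool qual = overlap >= min_overlap &&
                        (double)(overlap - mm) >= min_identity * (double) overlap;
                    int matches = overlap - mm;
                    int bmatches = best.overlap - best.mm;
                    bool better = !have ||
                        (qual && !bestq) ||
                        (qual == bestq && (matches > bmatches ||
                         (matches == bmatches && mm < best.mm) ||
                         (matches == bmatches && mm == best.mm && diags[d] < best.off)));
                    if (better) {
                        best.contig = j; best.strand = (s == 0) ? 1 : -1;
                        best.off = diags[d]; best.overlap = overlap; best.mm = mm;
                        have = true; bestq = qual;
                    }
                }
            }
            if (have) {
                o_read.push_back(i + 1); o_contig.push_back(j + 1);
                o_strand.push_back(best.strand); o_off.push_back(best.off);
                o_ov.push_back(best.overlap); o_mm.push_back(best.mm);
                o_q.push_back(bestq ? 1 : 0);
            }
        }
    }
    return DataFrame::create(_["read"] = o_read, _["contig"] = o_contig,
                             _["strand"] = o_strand, _["offset"] = o_off,
                             _["overlap"] = o_ov, _["mismatches"] = o_mm,
                             _["qualified"] = o_q);
}

// Anchor scan for low-stringency verification. For each read, the single best
// placement across all contigs/strands is located; within its overlap the
// longest perfect-match run is the anchor. Off-anchor disagreement is
// reported separately left and right of the anchor (overhang beyond the
// contig excluded). One row per read with any seed hit.
// [[Rcpp::export]]
DataFrame cpp_anchor_scan(CharacterVector reads, CharacterVector contigs, int k) {
    int nc = contigs.size(), nr = reads.size();
    std::vector<std::string> cseq(nc);
    std::vector<KmerIndex> idx(nc);
    for (int j = 0; j < nc; ++j) {
        cseq[j] = as<std::string>(contigs[j]);
        idx[j] = build_index(cseq[j], k);
    }
    std::vector<int> o_read, o_contig, o_strand, o_off, o_ov, o_mm,
        o_run_s, o_run_e, o_mm_l, o_len_l, o_mm_r, o_len_r;
    for (int i = 0; i < nr; ++i) {
        std::string fwd = as<std::string>(reads[i]);
        std::string rev = revcomp(fwd);
        bool have = false; Hit best; best.mm = 0; best.overlap = 0;
        for (int j = 0; j < nc; ++j) {
            for (int s = 0; s < 2; ++s) {
                const std::string& r = (s == 0) ? fwd : rev;
                std::vector<int> diags;
                candidate_diags(r, idx[j], k, diags);
                for (size_t d = 0; d < diags.size(); ++d) {
                    int overlap, mm;
                    overlap_mm(r, cseq[j], diags[d], overlap, mm);
                    if (overlap <= 0) continue;
                    int matches = overlap - mm;
                    int bmatches = best.overlap - best.mm;
                    bool better = !have || matches > bmatches ||
                        (matches == bmatches && mm < best.mm);
                    if (better) {
                        best.contig = j; best.strand = (s == 0) ? 1 : -1;
                        best.off = diags[d]; best.overlap = overlap; best.mm = mm;
                        have = true;
                    }
                }
            }
        }
        if (!have) continue;
        const std::string& r = (best.strand == 1) ? fwd : rev;
        const std::string& c = cseq[best.contig];
        int rl = (int) r.size();
        int rs = std::max(0, -best.off), re = std::min(rl, (int) c.size() - best.off);
        // longest perfect run within [rs, re)
        int run_s = rs, run_e = rs, cur_s = rs, best_len = 0;
        for (int p = rs; p <= re; ++p) {
            bool match = false;
            if (p < re) {
                int ai = base2int(r[p]), bi = base2int(c[best.off + p]);
                match = (ai <= 3 && bi <= 3 && ai == bi);
            }
            if (!match) {
                if (p - cur_s > best_len) { best_len = p - cur_s; run_s = cur_s; run_e = p; }
                cur_s = p + 1;
            }
        }
        int mm_l = 0, mm_r = 0;
        for (int p = rs; p < run_s; ++p) {
            int ai = base2int(r[p]), bi = base2int(c[best.off + p]);
            if (ai > 3 || bi > 3 || ai != bi) ++mm_l;
        }
        for (int p = run_e; p < re; ++p) {
            int ai = base2int(r[p]), bi = base2int(c[best.off + p]);
            if (ai > 3 || bi > 3 || ai != bi) ++mm_r;
        }
        o_read.push_back(i + 1); o_contig.push_back(best.contig + 1);
        o_strand.push_back(best.strand); o_off.push_back(best.off);
        o_ov.push_back(best.overlap); o_mm.push_back(best.mm);
        o_run_s.push_back(best.off + run_s);       // 0-based contig coord of anchor start
        o_run_e.push_back(best.off + run_e);       // 0-based exclusive end
        o_mm_l.push_back(mm_l); o_len_l.push_back(run_s - rs);
        o_mm_r.push_back(mm_r); o_len_r.push_back(re - run_e);
    }
    return DataFrame::create(_["read"] = o_read, _["contig"] = o_contig,
                             _["strand"] = o_strand, _["offset"] = o_off,
                             _["overlap"] = o_ov, _["mismatches"] = o_mm,
                             _["anchor_start"] = o_run_s, _["anchor_end"] = o_run_e,
                             _["mm_left"] = o_mm_l, _["len_left"] = o_len_l,
                             _["mm_right"] = o_mm_r, _["len_right"] = o_len_r);
}

// Base counts (A,C,G,T,other) per column for oriented reads placed at 0-based
// offsets relative to a region of length region_len.
// [[Rcpp::export]]
IntegerMatrix cpp_pileup(CharacterVector reads, IntegerVector offsets, int region_len) {
    IntegerMatrix counts(5, region_len);
    int nr = reads.size();
    for (int i = 0; i < nr; ++i) {
        std::string r = as<std::string>(reads[i]);
        int off = offsets[i];
        for (int p = 0; p < (int) r.size(); ++p) {
            int col = off + p;
            if (col < 0 || col >= region_len) continue;
            counts(base2int(r[p]), col)++;
        }
    }
    return counts;
}

// Overlap length and mismatch count of `read` placed at 0-based `offset` on
// `contig` (ungapped). Scalar helper backing accept_hit().
// [[Rcpp::export]]
IntegerVector cpp_overlap_mm(std::string read, std::string contig, int offset) {
    int overlap, mm;
    overlap_mm(read, contig, offset, overlap, mm);
    return IntegerVector::create(_["overlap"] = overlap, _["mismatches"] = mm);
}

// Greedy seed-stage paralog grouping. Reads (already oriented to the
// reference's forward strand) arrive in a fixed order with reference
// offsets; each read joins the best existing group whose current majority
// consensus it matches under the high-stringency acceptance rule, founds a
// new group when its best identity falls at or below founder_max_identity
// (or when it overlaps no group by at least min_overlap), and is otherwise
// deferred. Ties on mismatch count are flagged ambiguous: such reads add
// coverage to all tied groups but are assigned to the lowest-index one.
// Returns per-read group (0 = deferred), ambiguity flag, and per-read list
// of groups whose counts it entered.
// [[Rcpp::export]]
List cpp_seed_groups(CharacterVector reads, IntegerVector offsets, IntegerVector order,
                     int ref_len, int min_overlap, double min_identity,
                     double max_mismatch_fraction, double founder_max_identity) {
    int nr = reads.size();
    std::vector<std::string> rs(nr);
    for (int i = 0; i < nr; ++i) rs[i] = as<std::string>(reads[i]);
    std::vector<std::vector<int> > counts; // group -> flattened 5 x ref_len
    std::vector<int> group(nr, 0);
    std::vector<int> ambig(nr, 0);
    List contrib(nr);

    for (int oi = 0; oi < (int) order.size(); ++oi) {
        int i = order[oi] - 1;
        const std::string& r = rs[i];
        int off = offsets[i], rl = (int) r.size();
        int ng = (int) counts.size();
        int best_mm = -1, best_g = -1, best_ov = 0;
        std::vector<int> tied;
        for (int g = 0; g < ng; ++g) {
            // overlap with group's covered columns; mismatches vs majority
            int ov = 0, mm = 0;
            for (int p = 0; p < rl; ++p) {
                int col = off + p;
                if (col < 0 || col >= ref_len) continue;
                const std::vector<int>& cc = counts[g];
                int tot = cc[0 * ref_len + col] + cc[1 * ref_len + col] +
                          cc[2 * ref_len + col] + cc[3 * ref_len + col] +
                          cc[4 * ref_len + col];
                if (tot == 0) continue;
                ++ov;
                int maj = 0, majc = -1;
                for (int b = 0; b < 4; ++b)
                    if (cc[b * ref_len + col] > majc) { majc = cc[b * ref_len + col]; maj = b; }
                int rb = base2int(r[p]);
                if (rb > 3 || rb != maj) ++mm;
            }
            if (ov < min_overlap) continue;
            bool better = (best_g < 0) ||
                (mm * best_ov < best_mm * ov) ||  // compare mm/ov rates
                (mm * best_ov == best_mm * ov && ov > best_ov);
            if (better) { best_g = g; best_mm = mm; best_ov = ov; tied.clear(); tied.push_back(g); }
            else if (best_g >= 0 && mm * best_ov == best_mm * ov && ov == best_ov) tied.push_back(g);
        }
        bool accepted = false;
        if (best_g >= 0) {
            double ident = 1.0 - (double) best_mm / (double) best_ov;
            int cap = (int) std::floor(max_mismatch_fraction * best_ov);
            accepted = (best_ov >= min_overlap) && (ident >= min_identity) && (best_mm <= cap);
        }
        std::vector<int> touched;
        if (accepted) {
            group[i] = best_g + 1;
            if (tied.size() > 1) ambig[i] = 1;
            for (size_t t = 0; t < tied.size(); ++t) {
                std::vector<int>& cc = counts[tied[t]];
                for (int p = 0; p < rl; ++p) {
                    int col = off + p;
                    if (col < 0 || col >= ref_len) continue;
                    cc[base2int(r[p]) * ref_len + col]++;
                }
                touched.push_back(tied[t] + 1);
            }
            group[i] = tied[0] + 1;
        } else {
            double best_ident = (best_g >= 0) ? 1.0 - (double) best_mm / (double) best_ov : -1.0;
            if (best_g < 0 || best_ident <= founder_max_identity) {
                counts.push_back(std::vector<int>(5 * ref_len, 0));
                std::vector<int>& cc = counts.back();
                for (int p = 0; p < rl; ++p) {
                    int col = off + p;
                    if (col < 0 || col >= ref_len) continue;
                    cc[base2int(r[p]) * ref_len + col]++;
                }
                group[i] = (int) counts.size();
                touched.push_back((int) counts.size());
            } // else deferred: group stays 0
        }
        contrib[i] = wrap(touched);
    }
    return List::create(_["group"] = wrap(group), _["ambiguous"] = wrap(ambig),
                        _["n_groups"] = (int) counts.size(), _["contrib"] = contrib);
}
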