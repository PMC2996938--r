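#include <Rcpp.h>
#include <string>
#include <vector>
#include <unordered_map>
#include <unordered_set>
#include <cstdint>
using namespace Rcpp;

// Hermetic end-to-end read mapper for desk-scale references.
//
// Seed-and-verify with exact k-mer seeds: a read of length len with at most
// max_mismatch substitutions is guaranteed to be found as long as it carries
// max_mismatch + 1 disjoint seed windows of length k (pigeonhole: one window
// is error-free). The caller groups reads by length and passes
// k = floor(len / (max_mismatch + 1)). Non-ACGT characters (e.g. 'N') never
// match and count as mismatches; seeds containing them are skipped, which is
// safe because N positions count toward the mismatch budget.

static inline int enc(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
    }
}

static inline char comp(char c) {
    switch (c) {
    case 'A': case 'a': return 'T';
    case 'C': case 'c': return 'G';
    case 'G': case 'g': return 'C';
    case 'T': case 't': return 'A';
    default: return 'N';
    }
}

static std::string revcomp(const std::string& s) {
    std::string r(s.rbegin(), s.rend());
    for (size_t i = 0; i < r.size(); ++i) r[i] = comp(r[i]);
    return r;
}

//' @noRd
// [[Rcpp::export(name = ".toymap_batch")]]
DataFrame toymap_batch(CharacterVector reads, CharacterVector refs,
                       int k, int max_mismatch) {
    const int nref = refs.size();
    std::vector<std::string> R(nref);
    for (int c = 0; c < nref; ++c) R[c] = as<std::string>(refs[c]);

    // k-mer index over all reference sequences; key = 2-bit packed k-mer,
    // value = packed (ref << 40) | 0-based position
    std::unordered_map<uint64_t, std::vector<uint64_t> > idx;
    idx.reserve(1 << 20);
    for (int c = 0; c < nref; ++c) {
        const std::string& s = R[c];
        if ((int)s.size() < k) continue;
        uint64_t key = 0, mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
        int valid = 0;
        for (size_t i = 0; i < s.size(); ++i) {
            int e = enc(s[i]);
            if (e < 0) { valid = 0; key = 0; continue; }
            key = ((key << 2) | (uint64_t)e) & mask;
            if (++valid >= k)
                idx[key].push_back(((uint64_t)c << 40) | (uint64_t)(i - k + 1));
        }
    }

    std::vector<int> out_read, out_ref, out_pos, out_mm;
    std::vector<char> out_strand;

    const int nreads = reads.size();
    for (int r = 0; r < nreads; ++r) {
        if (CharacterVector::is_na(reads[r])) continue;
        std::string fwd = as<std::string>(reads[r]);
        const int len = (int)fwd.size();
        if (len < k) continue;
        std::string rc = revcomp(fwd);
        std::unordered_set<uint64_t> seen;
        for (int ori = 0; ori < 2; ++ori) {
            const std::string& q = ori ? rc : fwd;
            for (int s = 0; s <= max_mismatch; ++s) {
                int off = s * k;
                if (off + k > len) break;
                uint64_t key = 0;
                bool ok = true;
                for (int j = 0; j < k; ++j) {
                    int e = enc(q[off + j]);
                    if (e < 0) { ok = false; break; }
                    key = (key << 2) | (uint64_t)e;
                }
                if (!ok) continue;
                std::unordered_map<uint64_t, std::vector<uint64_t> >::const_iterator
                    it = idx.find(key);
                if (it == idx.end()) continue;
                for (size_t h = 0; h < it->second.size(); ++h) {
                    int c = (int)(it->second[h] >> 40);
                    long p = (long)(it->second[h] & ((1ULL << 40) - 1)) - off;
                    if (p < 0 || p + len > (long)R[c].size()) continue;
                    uint64_t sig = ((uint64_t)ori << 63) | ((uint64_t)c << 40) |
                                   (uint64_t)p;
                    if (seen.count(sig)) continue;
                    const std::string& chrom = R[c];
                    int mm = 0;
                    for (int j = 0; j < len; ++j) {
                        int a = enc(q[j]), b = enc(chrom[p + j]);
                        if (a < 0 || a != b) { if (++mm > max_mismatch) break; }
                    }
                    if (mm <= max_mismatch) {
                        seen.insert(sig);
                        out_read.push_back(r + 1);
                        out_ref.push_back(c + 1);
                        out_pos.push_back((int)p + 1);
                        out_strand.push_back(ori ? '-' : '+');
                        out_mm.push_back(mm);
                    }
                }
            }
        }
    }

    CharacterVector strand(out_strand.size());
    for (size_t i = 0; i < out_strand.size(); ++i)
        strand[i] = std::string(1, out_strand[i]);
    return DataFrame::create(_["read"] = wrap(out_read),
                             _["ref"] = wrap(out_ref),
                             _["pos"] = wrap(out_pos),
                             _["strand"] = strand,
                             _["mismatches"] = wrap(out_mm),
                             _["stringsAsFactors"] = false);
}
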