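#include <Rcpp.h>
#include <map>
#include <string>
#include <vector>
using namespace Rcpp;

// Depth-first trie enumeration of the k-mers whose summed profile score
// at a position is strictly below theta. Children are visited in order of
// ascending column score, so the first partial sum reaching theta prunes
// the remaining siblings as well (scores are non-negative).
// [[Rcpp::export(name = ".feature_map_cpp")]]
IntegerVector feature_map_cpp(NumericMatrix scores, int k, double theta,
                              CharacterVector alphabet) {
  const int L = scores.nrow();
  const int A = scores.ncol();
  if (k < 1) stop("k must be >= 1");
  if (L < k) stop("profile shorter than k");

  std::vector<char> letters(A);
  for (int a = 0; a < A; ++a) letters[a] = CHAR(STRING_ELT(alphabet, a))[0];

  // per-row letter order, ascending by score
  std::vector<std::vector<int> > ord(L, std::vector<int>(A));
  for (int i = 0; i < L; ++i) {
    std::vector<int>& o = ord[i];
    for (int a = 0; a < A; ++a) o[a] = a;
    NumericMatrix::Row row = scores(i, _);
    std::sort(o.begin(), o.end(),
              [&](int x, int y) { return row[x] < row[y]; });
  }

  std::map<std::string, int> counts;
  std::string buf(k, ' ');
  // explicit stack of (depth, child index within ord, partial score)
  std::vector<int> child(k);
  std::vector<double> partial(k + 1);

  for (int pos = 0; pos + k <= L; ++pos) {
    int d = 0;
    child[0] = 0;
    partial[0] = 0.0;
    while (d >= 0) {
      if (child[d] >= A) { --d; if (d >= 0) ++child[d]; continue; }
      const int a = ord[pos + d][child[d]];
      const double s = partial[d] + scores(pos + d, a);
      if (s >= theta) { // ascending order: no later sibling can pass
        --d; if (d >= 0) ++child[d];
        continue;
      }
      buf[d] = letters[a];
      if (d == k - 1) {
        counts[buf]++;
        ++child[d];
      } else {
        partial[d + 1] = s;
        ++d;
        child[d] = 0;
      }
    }
  }

  IntegerVector out(counts.size());
  CharacterVector nm(counts.size());
  int i = 0;
  for (std::map<std::string, int>::const_iterator it = counts.begin();
       it != counts.end(); ++it, ++i) {
    nm[i] = it->first;
    out[i] = it->second;
  }
  out.names() = nm;
  return out;
}
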