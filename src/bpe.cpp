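#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
using namespace Rcpp;

// Token ids follow the package convention: 0 = EOS (never present in the
// training sequences), 1..B = base symbols, B+1.. = merged tokens.

static inline long long pairKey(int a, int b) {
  return (static_cast<long long>(a) << 32) | static_cast<unsigned int>(b);
}

// Train BPE merges. `corpus` holds integer vectors of base-symbol ids,
// `tokenStrings` the id->string table (index 0 = EOS placeholder). Merges the
// most frequent adjacent pair (ties: lexicographically smallest concatenated
// string, then left string, then right string) until `targetMerges` merges
// are made or no pair occurs at least twice. Pairs never span sequences.
// [[Rcpp::export]]
List cpp_bpe_train(List corpus, CharacterVector tokenStrings, int targetMerges) {
  std::vector<std::vector<int>> seqs;
  seqs.reserve(corpus.size());
  for (int i = 0; i < corpus.size(); ++i) {
    IntegerVector v = corpus[i];
    seqs.emplace_back(v.begin(), v.end());
  }
  std::vector<std::string> toks;
  toks.reserve(tokenStrings.size() + targetMerges);
  for (int i = 0; i < tokenStrings.size(); ++i)
    toks.push_back(as<std::string>(tokenStrings[i]));

  std::vector<int> mleft, mright, mnew;
  for (int m = 0; m < targetMerges; ++m) {
    std::unordered_map<long long, int> counts;
    for (const auto& s : seqs)
      for (size_t j = 1; j < s.size(); ++j)
        counts[pairKey(s[j - 1], s[j])]++;
    int bestA = -1, bestB = -1, bestC = 1; // require count >= 2
    std::string bestCat, bestL, bestR;
    for (const auto& kv : counts) {
      if (kv.second < 2) continue;
      int a = static_cast<int>(kv.first >> 32);
      int b = static_cast<int>(kv.first & 0xffffffffLL);
      std::string cat = toks[a] + toks[b];
      bool take = false;
      if (kv.second > bestC) take = true;
      else if (kv.second == bestC && bestA >= 0) {
        if (cat < bestCat) take = true;
        else if (cat == bestCat) {
          if (toks[a] < bestL) take = true;
          else if (toks[a] == bestL && toks[b] < bestR) take = true;
        }
      } else if (kv.second == bestC && bestA < 0) take = true;
      if (take) {
        bestA = a; bestB = b; bestC = kv.second;
        bestCat = cat; bestL = toks[a]; bestR = toks[b];
      }
    }
    if (bestA < 0) break;
    int newId = static_cast<int>(toks.size());
    toks.push_back(bestCat);
    mleft.push_back(bestA); mright.push_back(bestB); mnew.push_back(newId);
    for (auto& s : seqs) {
      size_t w = 0;
      for (size_t j = 0; j < s.size(); ) {
        if (j + 1 < s.size() && s[j] == bestA && s[j + 1] == bestB) {
          s[w++] = newId; j += 2;
        } else {
          s[w++] = s[j++];
        }
      }
      s.resize(w);
    }
  }
  return List::create(
    _["left"] = wrap(mleft), _["right"] = wrap(mright), _["newid"] = wrap(mnew),
    _["tokens"] = wrap(toks));
}

static std::vector<int> encodeOne(std::vector<int> s,
    const std::unordered_map<long long, std::pair<int,int>>& ranks) {
  // Repeatedly apply the lowest-rank merge present, all occurrences
  // leftmost-first, until no merge applies.
  for (;;) {
    int bestRank = -1; long long bestKey = 0;
    for (size_t j = 1; j < s.size(); ++j) {
      auto it = ranks.find(pairKey(s[j - 1], s[j]));
      if (it != ranks.end() &&
          (bestRank < 0 || it->second.first < bestRank)) {
        bestRank = it->second.first; bestKey = pairKey(s[j - 1], s[j]);
      }
    }
    if (bestRank < 0) break;
    int a = static_cast<int>(bestKey >> 32);
    int b = static_cast<int>(bestKey & 0xffffffffLL);
    int newId = ranks.at(bestKey).second;
    size_t w = 0;
    for (size_t j = 0; j < s.size(); ) {
      if (j + 1 < s.size() && s[j] == a && s[j + 1] == b) {
        s[w++] = newId; j += 2;
      } else s[w++] = s[j++];
    }
    s.resize(w);
  }
  return s;
}

// [[Rcpp::export]]
List cpp_bpe_encode_many(List seqs, IntegerVector left, IntegerVector right,
                         IntegerVector newid) {
  std::unordered_map<long long, std::pair<int,int>> ranks;
  for (int i = 0; i < left.size(); ++i)
    ranks[pairKey(left[i], right[i])] = std::make_pair(i, newid[i]);
  List out(seqs.size());
  for (int i = 0; i < seqs.size(); ++i) {
    IntegerVector v = seqs[i];
    std::vector<int> s(v.begin(), v.end());
    out[i] = wrap(encodeOne(std::move(s), ranks));
  }
  return out;
}
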