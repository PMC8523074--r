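# Frozen schema lexicons for the synthetic corpus generator.
#
# Nine pairwise-disjoint themed word lists (one per schema, echoing the kind
# of vocabulary typical of each schema's utterances) plus one neutral list.
# These are fixtures for generating lexicon-mixture text with known ground
# truth -- not claims about English usage. They are chosen to survive the
# default preprocessing chain (lower-case, no punctuation, no stop words).

#' Default schema lexicons
#'
#' @return Named list of ten character vectors: one per schema (canonical
#'   order) plus `neutral`. The nine schema lists are pairwise disjoint.
#' @export
default_lexicons <- function() {
  lex <- list(
    attachment = c(
      "unlovable", "alone", "lonely", "friends", "girlfriend", "partner",
      "relationship", "unwanted", "abandoned", "rejected", "unlikeable",
      "family", "belong", "isolated", "companionship", "bond", "distant",
      "attachment", "closeness", "outcast", "friendless", "deserted"),
    competence = c(
      "failure", "job", "task", "incompetent", "unprepared", "skills",
      "succeed", "career", "capable", "useless", "fired", "promotion",
      "deadline", "qualified", "achieve", "project", "sales", "ability",
      "perform", "bungle", "unemployable", "inept"),
    global_self_evaluation = c(
      "lazy", "selfish", "worthless", "stupid", "terrible", "awful",
      "flawed", "inadequate", "shameful", "pathetic", "loser", "horrible",
      "undeserving", "broken", "disgrace", "rotten", "defective",
      "contemptible"),
    health = c(
      "ill", "sick", "weight", "diet", "fat", "overweight", "exhausted",
      "disease", "counseling", "unhealthy", "pain", "dying", "body",
      "doctor", "medication", "skinny", "anxious", "depressed", "symptoms",
      "illness"),
    power_control = c(
      "stuck", "control", "trapped", "pressured", "helpless", "forced",
      "powerless", "boss", "abuse", "victim", "dominated", "escape",
      "freedom", "cornered", "oppressed", "overruled", "captive",
      "subjugated"),
    meta_cognition = c(
      "perception", "compulsive", "thoughts", "thinking", "obsess",
      "overthink", "mind", "believing", "irrational", "paranoid",
      "distorted", "ruminate", "misjudge", "biased", "delusional",
      "introspection"),
    other_people = c(
      "people", "others", "cruel", "mock", "avoid", "despicable", "mean",
      "uncaring", "rude", "untrustworthy", "heartless", "inconsiderate",
      "hostile", "malicious", "spiteful", "callous", "unaccountable"),
    hopelessness = c(
      "hopeless", "never", "quit", "purpose", "future", "pointless",
      "dead", "despair", "enjoy", "meaningless", "doomed", "forever",
      "bleak", "futile", "worthwhile", "resign", "grim"),
    others_views_on_self = c(
      "opinion", "impression", "respect", "reputation", "embarrassed",
      "judged", "disapprove", "laughingstock", "ridiculed", "image",
      "admired", "unimpressive", "perceived", "scorned", "belittled",
      "humiliated", "dismissed"),
    neutral = c(
      "situation", "today", "really", "thing", "happen", "moment", "time",
      "feel", "maybe", "something", "wonder", "quite", "little", "walk",
      "street", "see", "around", "nearby", "often", "yesterday", "perhaps",
      "somehow", "things", "felt")
  )
  lex
}
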