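# Demo topic vocabulary: keyword -> topic(s) mapping used by the interest
# extractor. Same content as synthetic_vocabulary(), in the on-disk format
# accepted by read_vocabulary().
topics:
  - nutrition
  - fitness
  - body_image
  - recovery
  - wellbeing
  - music
  - gaming
  - news
keywords:
  calories: nutrition
  diet: nutrition
  fasting: nutrition
  meal: nutrition
  carbs: nutrition
  sugar: nutrition
  vegan: nutrition
  recipes: nutrition
  exercise: fitness
  workout: fitness
  running: fitness
  gym: fitness
  cardio: fitness
  steps: fitness
  training: fitness
  sweat: fitness
  thin: body_image
  weight: body_image
  mirror: body_image
  skinny: body_image
  waist: body_image
  scale: body_image
  bones: body_image
  collarbone: body_image
  recovery: recovery
  therapy: recovery
  healing: recovery
  support: recovery
  relapse: recovery
  treatment: recovery
  hope: recovery
  progress: recovery
  mindfulness: wellbeing
  sleep: wellbeing
  balance: wellbeing
  selfcare: wellbeing
  breathing: wellbeing
  journal: wellbeing
  calm: wellbeing
  gratitude: wellbeing
  guitar: music
  concert: music
  playlist: music
  album: music
  band: music
  lyrics: music
  piano: music
  festival: music
  playstation: gaming
  console: gaming
  gamer: gaming
  quest: gaming
  pixel: gaming
  arcade: gaming
  level: gaming
  stream: gaming
  headline: news
  politics: news
  election: news
  economy: news
  weather: news
  report: news
  press: news
  media: news
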